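#' Gaussian log-likelihood of log reaction times given a value trace
#'
#' Evaluates the regression likelihood
#' `LL = n log(1 / (sqrt(2 pi) sigma)) - 1/(2 sigma^2) sum (rt_t - b0 - b1 v_t)^2`
#' over the trials that enter the fit (by default, trials with a response,
#' since only those have a reaction time). With `sigma = "profile"` the
#' residual SD is set to its maximum-likelihood value, the root-mean-square
#' residual, floored at `sigma_floor` to keep noiseless synthetic data from
#' degenerating.
#'
#' @param data Behavioral data.frame with columns `responded` and `log_rt`
#'   (log seconds; NA when no response occurred), aligned row-for-row with
#'   `trace`.
#' @param trace A `value_trace` from [run_model()] (only its `v` column is
#'   used). For the no-learning model pass any trace; the slope is ignored
#'   when `beta[2]` is 0.
#' @param beta Numeric `c(intercept, value_slope)`.
#' @param sigma Positive residual SD, or `"profile"`.
#' @param inclusion `"responded"` (default) or `"all"` (requires every trial
#'   to have a finite `log_rt`).
#' @param sigma_floor Lower bound for the profiled SD (default 1e-4).
#' @return Scalar log-likelihood in nats, with attributes `sigma` (the SD
#'   used) and `n` (number of included trials).
#' @export
rt_log_likelihood <- function(data, trace, beta, sigma = "profile",
                              inclusion = c("responded", "all"),
                              sigma_floor = 1e-4) {
  inclusion <- match.arg(inclusion)
  if (nrow(data) != nrow(trace)) {
    stop("data and trace are not aligned", call. = FALSE)
  }
  keep <- if (inclusion == "responded") data$responded == 1 else
    rep(TRUE, nrow(data))
  y <- data$log_rt[keep]
  if (length(y) == 0) stop("no included trials", call. = FALSE)
  if (any(!is.finite(y))) stop("included trials must have finite log_rt",
                               call. = FALSE)
  resid <- y - (beta[1] + beta[2] * trace$v[keep])
  n <- length(y)
  if (identical(sigma, "profile")) {
    sigma <- max(sqrt(mean(resid^2)), sigma_floor)
  } else if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be positive or \"profile\"", call. = FALSE)
  }
  ll <- n * log(1 / (sqrt(2 * pi) * sigma)) - sum(resid^2) / (2 * sigma^2)
  structure(ll, sigma = sigma, n = n)
}

# Profiled regression step: given values v and log RTs y, the ML beta is the
# OLS solution and the ML sigma the RMS residual. Falls back to an
# intercept-only fit when v is (numerically) constant, which happens e.g.
# for alpha = 0 with v0 = 0 and for the no-learning model.
profile_regression <- function(y, v, sigma_floor = 1e-4,
                               slope = TRUE) {
  n <- length(y)
  if (slope && stats::sd(v) > 1e-10) {
    vm <- mean(v); ym <- mean(y)
    b1 <- sum((v - vm) * (y - ym)) / sum((v - vm)^2)
    b0 <- ym - b1 * vm
  } else {
    b0 <- mean(y); b1 <- 0
  }
  resid <- y - b0 - b1 * v
  sigma <- max(sqrt(mean(resid^2)), sigma_floor)
  ll <- n * log(1 / (sqrt(2 * pi) * sigma)) - sum(resid^2) / (2 * sigma^2)
  list(beta = c(b0, b1), sigma = sigma, ll = ll)
}

included_index <- function(data, inclusion) {
  keep <- if (inclusion == "responded") data$responded == 1 else
    rep(TRUE, nrow(data))
  if (any(!is.finite(data$log_rt[keep]))) {
    stop("included trials must have finite log_rt", call. = FALSE)
  }
  keep
}

#' Jointly fit a learning model and the reaction-time regression
#'
#' Maximizes the regression likelihood over the model's learning parameters
#' (alpha, and omega for the value-spread model, optionally the initial
#' value v0) with the regression weights and residual SD profiled out in
#' closed form at every candidate. The learning parameters are optimized by
#' bounded quasi-Newton (L-BFGS-B) from `n_restarts` seeded starting points;
#' the best restart is returned, with ties broken by first occurrence.
#'
#' @param data Behavioral data.frame: columns run, trial, stimulus, target,
#'   responded, log_rt.
#' @param model_kind Model name (see [model_params()]).
#' @param n_restarts Number of random restarts (default 20).
#' @param seed Integer seed for the restart draws.
#' @param free_v0 Also fit the initial value, bounded to \[0, 1\]
#'   (default FALSE: v0 = 0).
#' @param v0 Initial value when not free.
#' @param inclusion Trial-inclusion rule passed to the likelihood.
#' @param reset_between_runs Passed to [run_model()].
#' @param sigma_floor Floor for the profiled residual SD.
#' @return A `fit_result` list: `params` (fitted [model_params()]),
#'   `log_likelihood`, `per_run_ll`, `n_included`, `converged`,
#'   `n_restarts`, `model_kind`, `free_v0`.
#' @export
fit_model <- function(data, model_kind, n_restarts = 20, seed = 1,
                      free_v0 = FALSE, v0 = 0,
                      inclusion = c("responded", "all"),
                      reset_between_runs = TRUE, sigma_floor = 1e-4) {
  inclusion <- match.arg(inclusion)
  data <- data[order(data$run, data$trial), , drop = FALSE]
  keep <- included_index(data, inclusion)
  y <- data$log_rt[keep]
  if (length(y) < 3) stop("too few included trials to fit", call. = FALSE)
  k_rl <- n_rl_params(model_kind)
  has_slope <- model_kind != "no_learning"
  prep <- prep_sequence(data, reset_between_runs)

  objective <- function(theta) {
    v0_t <- if (free_v0) theta[length(theta)] else v0
    tr <- trace_values(prep, model_kind,
                       a = if (k_rl >= 1) theta[1] else 0,
                       w = if (model_kind == "value_spread") theta[2] else 0,
                       v0 = v0_t)
    fit <- profile_regression(y, tr$v[keep], sigma_floor, has_slope)
    -fit$ll
  }

  n_free <- k_rl + if (free_v0) 1L else 0L
  if (n_free == 0L) {
    fit <- profile_regression(y, numeric(length(y)), sigma_floor, FALSE)
    best <- list(theta = numeric(0), value = -fit$ll, convergence = 0)
  } else {
    set.seed(as.integer(seed))
    lower <- rep(0, n_free); upper <- rep(1, n_free)
    starts <- matrix(stats::runif(n_restarts * n_free), ncol = n_free)
    best <- NULL
    any_converged <- FALSE
    for (i in seq_len(n_restarts)) {
      opt <- tryCatch(
        stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (opt$convergence == 0) any_converged <- TRUE
      if (is.null(best) || opt$value < best$value - 1e-12) {
        best <- list(theta = opt$par, value = opt$value,
                     convergence = opt$convergence)
      }
    }
    if (is.null(best)) {
      stop("all restarts failed for model '", model_kind, "'", call. = FALSE)
    }
    best$convergence <- if (any_converged) 0 else 1
  }

  pars <- theta_to_params(model_kind, best$theta, free_v0, v0)
  trace <- run_model(data, pars, reset_between_runs)
  prof <- profile_regression(y, trace$v[keep], sigma_floor, has_slope)
  pars$beta <- prof$beta
  pars$sigma <- prof$sigma
  per_run <- vapply(sort(unique(data$run)), function(r) {
    idx <- data$run == r & keep
    if (!any(idx)) return(NA_real_)
    resid <- data$log_rt[idx] - (prof$beta[1] + prof$beta[2] * trace$v[idx])
    sum(stats::dnorm(resid, 0, prof$sigma, log = TRUE))
  }, numeric(1))
  structure(list(model_kind = model_kind, params = pars,
                 log_likelihood = prof$ll,
                 per_run_ll = stats::setNames(per_run,
                                              sort(unique(data$run))),
                 n_included = sum(keep),
                 converged = best$convergence == 0,
                 n_restarts = n_restarts, free_v0 = free_v0,
                 inclusion = inclusion,
                 reset_between_runs = reset_between_runs,
                 sigma_floor = sigma_floor, seed = seed),
            class = "fit_result")
}

theta_to_params <- function(model_kind, theta, free_v0, v0_fixed) {
  v0 <- if (free_v0) theta[length(theta)] else v0_fixed
  switch(model_kind,
         no_learning = model_params("no_learning", v0 = v0),
         base_rate = model_params("base_rate", alpha = theta[1], v0 = v0),
         feature = model_params("feature", alpha = theta[1], v0 = v0),
         conjunctive = model_params("conjunctive", alpha = theta[1], v0 = v0),
         value_spread = model_params("value_spread", alpha = theta[1],
                                     omega = theta[2], v0 = v0))
}

#' Evaluate a fitted model's likelihood on (new) behavioral data
#'
#' Runs the fitted model on `data`'s trial sequence and evaluates the
#' regression likelihood at the fitted beta and sigma. Used by
#' cross-validation and by the per-run conjunctive-learning index.
#'
#' @param fit A `fit_result`.
#' @param data Behavioral data.frame (same format as for [fit_model()]).
#' @return Log-likelihood with attributes `sigma`, `n`.
#' @export
evaluate_fit <- function(fit, data) {
  data <- data[order(data$run, data$trial), , drop = FALSE]
  trace <- run_model(data, fit$params, fit$reset_between_runs)
  rt_log_likelihood(data, trace, fit$params$beta, fit$params$sigma,
                    inclusion = fit$inclusion,
                    sigma_floor = fit$sigma_floor)
}

#' Cross-validated predictive likelihood (leave-one-run-out)
#'
#' For each run, the model is fit on the remaining runs and the held-out
#' run's log reaction times are scored under the fitted parameters
#' (including the profiled sigma). The total held-out log-likelihood is
#' divided by the number of included held-out trials, normalizing across
#' differences in the number of responses.
#'
#' @inheritParams fit_model
#' @return List: `per_trial_ll` (mean held-out log-likelihood per trial),
#'   `total_ll`, `n`, `per_run` (held-out LL per run), `fits` (per-fold
#'   training fits).
#' @export
cv_predictive_likelihood <- function(data, model_kind, n_restarts = 20,
                                     seed = 1, free_v0 = FALSE,
                                     inclusion = c("responded", "all"),
                                     reset_between_runs = TRUE,
                                     sigma_floor = 1e-4) {
  inclusion <- match.arg(inclusion)
  runs <- sort(unique(data$run))
  if (length(runs) < 2) stop("cross-validation needs at least 2 runs",
                             call. = FALSE)
  per_run <- stats::setNames(numeric(length(runs)), runs)
  n_total <- 0L
  fits <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[i]
    train <- data[data$run != r, , drop = FALSE]
    test <- data[data$run == r, , drop = FALSE]
    fit <- fit_model(train, model_kind, n_restarts = n_restarts,
                     seed = seed + i, free_v0 = free_v0,
                     inclusion = inclusion,
                     reset_between_runs = reset_between_runs,
                     sigma_floor = sigma_floor)
    ll <- evaluate_fit(fit, test)
    per_run[i] <- as.numeric(ll)
    n_total <- n_total + attr(ll, "n")
    fits[[i]] <- fit
  }
  list(per_trial_ll = sum(per_run) / n_total, total_ll = sum(per_run),
       n = n_total, per_run = per_run, fits = fits,
       model_kind = model_kind)
}

#' Write behavioral data / fit results to disk
#'
#' Behavioral tables are TSV (run, trial, stimulus, target, responded,
#' rt, outcome ...); fit results go to JSON with parameters, likelihoods and
#' settings.
#'
#' @param data Behavioral data.frame.
#' @param path Output path.
#' @export
write_behavior_tsv <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @param fit A `fit_result`.
#' @export
write_fit_json <- function(fit, path) {
  out <- fit
  out$params <- unclass(out$params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
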