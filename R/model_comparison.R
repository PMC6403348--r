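#' Random-effects Bayesian model selection with protected exceedance
#' probabilities
#'
#' Treats the model generating each subject's data as drawn from an unknown
#' population distribution over models with a Dirichlet prior, and estimates
#' the posterior over model frequencies by variational Bayes. Reports the
#' posterior Dirichlet concentrations, expected model frequencies,
#' exceedance probabilities (the probability that each model is the most
#' frequent, estimated by Monte-Carlo sampling of the Dirichlet posterior),
#' the Bayesian omnibus risk (the posterior probability that all models are
#' equally frequent) and protected exceedance probabilities
#' `pep = xp * (1 - bor) + bor / K`, which sum to 1 across models.
#'
#' @param ev Subjects x models matrix of log model evidences. Cross-validated
#'   predictive log-likelihoods are the package's standard evidence proxy.
#' @param alpha0 Prior Dirichlet concentration (default 1: uniform).
#' @param n_mc Monte-Carlo samples for exceedance probabilities
#'   (default 1e6).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param max_iter,tol Variational iteration cap and convergence tolerance
#'   on the concentration change.
#' @return A `bms_result` list: `dirichlet_alpha`, `expected_freq`, `xp`,
#'   `bor`, `pep`, `model_names`, `n_mc_samples`, `seed`, `converged`.
#' @references Stephan et al. (2009) NeuroImage 46:1004-1017; Rigoux et al.
#'   (2014) NeuroImage 84:971-985.
#' @export
group_bms <- function(ev, alpha0 = 1, n_mc = 1e6, seed = 1,
                      max_iter = 500, tol = 1e-6) {
  ev <- as.matrix(ev)
  if (any(!is.finite(ev))) stop("evidence matrix must be finite",
                                call. = FALSE)
  if (nrow(ev) < 2 || ncol(ev) < 2) {
    stop("need at least 2 subjects and 2 models", call. = FALSE)
  }
  n <- nrow(ev); K <- ncol(ev)
  models <- colnames(ev)
  if (is.null(models)) models <- paste0("model", seq_len(K))
  a0 <- rep(alpha0, K)

  alpha <- a0 + n / K
  g <- matrix(1 / K, n, K)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- sweep(ev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw); g <- g / rowSums(g)
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }

  expected_freq <- alpha / sum(alpha)

  set.seed(as.integer(seed))
  draws <- matrix(stats::rgamma(n_mc * K, shape = rep(alpha, each = n_mc)),
                  nrow = n_mc, ncol = K)
  win <- max.col(draws, ties.method = "random")
  xp <- tabulate(win, nbins = K) / n_mc

  bor <- bms_bor(ev, alpha, g, a0)
  pep <- xp * (1 - bor) + bor / K

  structure(list(dirichlet_alpha = stats::setNames(alpha, models),
                 expected_freq = stats::setNames(expected_freq, models),
                 xp = stats::setNames(xp, models),
                 bor = bor,
                 pep = stats::setNames(pep, models),
                 model_names = models, n_mc_samples = n_mc, seed = seed,
                 converged = converged),
            class = "bms_result")
}

# Bayesian omnibus risk: posterior probability of the null hypothesis that
# all models are equally frequent, from the free energies of the null
# (fixed uniform frequencies) and the alternative (estimated frequencies).
bms_bor <- function(ev, alpha, g, a0) {
  K <- ncol(ev)
  log_c <- function(a) lgamma(sum(a)) - sum(lgamma(a))
  e_lnr <- digamma(alpha) - digamma(sum(alpha))
  g_safe <- pmax(g, 1e-300)
  f1 <- sum(g * ev) + sum(g %*% e_lnr) - sum(g * log(g_safe)) +
    log_c(a0) + sum((a0 - 1) * e_lnr) -
    (log_c(alpha) + sum((alpha - 1) * e_lnr))
  mx <- apply(ev, 1, max)
  f0 <- sum(mx + log(rowSums(exp(ev - mx))) - log(K))
  1 / (1 + exp(f1 - f0))
}

#' Paired Wilcoxon signed-rank comparison of per-subject likelihoods
#'
#' Two-sided signed-rank test on the paired differences of per-subject
#' (predictive) log-likelihoods. The reported statistic `T` is the smaller
#' of the positive- and negative-rank sums; the p-value uses the exact null
#' distribution for 25 or fewer non-zero differences and the normal
#' approximation otherwise. Zero differences are discarded; if all
#' differences are zero the comparison is degenerate and an error is
#' raised.
#'
#' @param ll_a,ll_b Equal-length numeric vectors (one entry per subject).
#' @return List: `T`, `p`, `n` (non-zero pairs), `direction` (sign of the
#'   median difference).
#' @export
pairwise_model_test <- function(ll_a, ll_b) {
  if (length(ll_a) != length(ll_b)) stop("paired vectors must have equal length",
                                         call. = FALSE)
  if (length(ll_a) < 5) stop("need at least 5 pairs", call. = FALSE)
  d <- ll_a - ll_b
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero: degenerate comparison",
                           call. = FALSE)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = !exact))
  list(T = min(w_pos, w_neg), p = wt$p.value, n = length(d),
       direction = sign(w_pos - w_neg))
}

#' Per-run conjunctive-learning index
#'
#' Quantifies, for each run, how much better the value-spread model accounts
#' for behavior than the pure conjunctive model, using each model's own
#' per-subject maximum-likelihood parameters. The index is the per-run
#' difference `LL_conjunctive - LL_value_spread`: 0 when the fitted spread
#' is zero (the models coincide) and increasingly negative the more value
#' spreading (i.e., the less purely conjunctive) the behavior is. The
#' engagement nuisance `LL_value_spread - LL_no_learning` measures how much
#' learning of any kind improved on a mean-only account, so that index
#' effects can be dissociated from overall task engagement.
#'
#' @param data Behavioral data.frame for one subject.
#' @param fit_value_spread,fit_conjunctive,fit_no_learning `fit_result`
#'   objects for the three models, fitted to the same subject across runs.
#' @return Data.frame: run, index, engagement, ll_conjunctive,
#'   ll_value_spread, ll_no_learning.
#' @export
conjunctive_learning_index <- function(data, fit_value_spread,
                                       fit_conjunctive, fit_no_learning) {
  stopifnot(inherits(fit_value_spread, "fit_result"),
            inherits(fit_conjunctive, "fit_result"),
            inherits(fit_no_learning, "fit_result"))
  runs <- sort(unique(data$run))
  per_run <- function(fit) {
    vapply(runs, function(r) {
      as.numeric(evaluate_fit(fit, data[data$run == r, , drop = FALSE]))
    }, numeric(1))
  }
  ll_vs <- per_run(fit_value_spread)
  ll_cj <- per_run(fit_conjunctive)
  ll_nl <- per_run(fit_no_learning)
  data.frame(run = runs,
             index = ll_cj - ll_vs,
             engagement = ll_vs - ll_nl,
             ll_conjunctive = ll_cj,
             ll_value_spread = ll_vs,
             ll_no_learning = ll_nl)
}

#' Write a BMS result as JSON
#' @param bms A `bms_result`.
#' @param path Output path.
#' @export
write_bms_json <- function(bms, path) {
  jsonlite::write_json(unclass(bms), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
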