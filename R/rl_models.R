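#' Model parameter container
#'
#' Bundles everything the learning rules and the reaction-time regression
#' need. Values represent the learned association between a stimulus and the
#' target (the probability that responding will be rewarded), not the
#' monetary outcome: updates are driven by the target indicator only.
#'
#' @param model_kind One of `"no_learning"`, `"base_rate"`, `"feature"`,
#'   `"conjunctive"`, `"value_spread"`.
#' @param alpha Learning rate in \[0, 1\].
#' @param omega Spread weight in \[0, 1\]; used only by the value-spread
#'   model, which leaks a fraction `omega` of each value update to every
#'   other stimulus sharing a feature with the presented one.
#' @param v0 Initial value assigned to every state at the start of a run.
#' @param beta Regression weights `c(intercept, value_slope)` mapping value
#'   to mean log reaction time.
#' @param sigma Residual SD of log reaction time (NA until fitted).
#' @return A `model_params` list.
#' @export
model_params <- function(model_kind = c("no_learning", "base_rate", "feature",
                                        "conjunctive", "value_spread"),
                         alpha = 0, omega = 0, v0 = 0,
                         beta = c(0, 0), sigma = NA_real_) {
  model_kind <- match.arg(model_kind)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]", call. = FALSE)
  if (!is.na(sigma) && sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(model_kind = model_kind, alpha = alpha, omega = omega,
                 v0 = v0, beta = beta, sigma = sigma),
            class = "model_params")
}

#' Number of free reinforcement-learning parameters of a model kind
#' @param model_kind Model name.
#' @keywords internal
n_rl_params <- function(model_kind) {
  switch(model_kind,
         no_learning = 0L,
         base_rate = 1L, feature = 1L, conjunctive = 1L,
         value_spread = 2L)
}

#' Initial value state for a model
#'
#' Feature learning keeps one value per feature (A, B, C); conjunctive and
#' value-spread learning keep one value per stimulus; base-rate learning
#' keeps a single value shared by all stimuli; the no-learning model has no
#' state (values are identically zero).
#'
#' @param params A [model_params()].
#' @return Named numeric vector of values, all equal to `params$v0`.
#' @export
init_values <- function(params) {
  keys <- switch(params$model_kind,
                 no_learning = character(0),
                 base_rate = "all",
                 feature = c("A", "B", "C"),
                 conjunctive = stimulus_names(),
                 value_spread = stimulus_names())
  stats::setNames(rep(params$v0, length(keys)), keys)
}

#' Predicted value of a stimulus under the current state
#'
#' For the feature model the prediction is the sum of the present features'
#' values (so V(AB) = V(A) + V(B)); for conjunctive/value-spread models it is
#' the value of the stimulus itself; base-rate uses its single value; the
#' no-learning model always predicts 0.
#'
#' @param values State vector from [init_values()] / [value_update()].
#' @param stimulus Stimulus name.
#' @param model_kind Model name.
#' @return Scalar predicted value.
#' @export
stimulus_value <- function(values, stimulus, model_kind) {
  switch(model_kind,
         no_learning = 0,
         base_rate = unname(values[["all"]]),
         feature = sum(values[stimulus_features()[[stimulus]]]),
         unname(values[[stimulus]]))
}

#' One delta-rule value update
#'
#' Applies the Rescorla-Wagner update V(s) <- V(s) + alpha * (R - V(s)) under
#' the representation of the given model. The feature model updates every
#' present feature by the full alpha * delta (delta computed from the summed
#' prediction); the value-spread model additionally adds
#' alpha * delta * omega to every other stimulus that shares a feature with
#' the presented one; the no-learning model leaves the (empty) state alone.
#'
#' @param values Current state vector.
#' @param stimulus Presented stimulus.
#' @param R Target indicator (0 or 1).
#' @param params A [model_params()].
#' @return Updated state vector.
#' @export
#' @examples
#' p <- model_params("value_spread", alpha = 0.5, omega = 0.5)
#' value_update(init_values(p), "AB", 1, p)
value_update <- function(values, stimulus, R, params) {
  if (!isTRUE(R %in% c(0, 1))) stop("R must be 0 or 1", call. = FALSE)
  assert_stimulus(stimulus)
  kind <- params$model_kind
  expected <- names(init_values(params))
  if (!identical(sort(names(values)), sort(expected)) &&
      kind != "no_learning") {
    stop("state keys do not match model kind '", kind, "'", call. = FALSE)
  }
  if (kind == "no_learning") return(values)
  a <- params$alpha
  delta <- R - stimulus_value(values, stimulus, kind)
  if (kind == "base_rate") {
    values[["all"]] <- values[["all"]] + a * delta
  } else if (kind == "feature") {
    for (f in stimulus_features()[[stimulus]]) {
      values[[f]] <- values[[f]] + a * delta
    }
  } else {
    values[[stimulus]] <- values[[stimulus]] + a * delta
    if (kind == "value_spread" && params$omega > 0) {
      for (s2 in stimulus_names()) {
        if (s2 != stimulus && feature_overlap(stimulus, s2) == 1L) {
          values[[s2]] <- values[[s2]] + a * delta * params$omega
        }
      }
    }
  }
  values
}

#' Run a learning model over a trial sequence
#'
#' Sequentially applies [value_update()] and records, for every trial, the
#' predicted value of the presented stimulus before the update (`v`), the
#' prediction error `delta = target - v`, and the stimulus value after the
#' update (`v_updated`, used by the pattern-similarity value regressor).
#' Because the category-to-feature mappings change between runs, the state
#' is re-initialized to `v0` at every run boundary by default.
#'
#' @param seq A [make_trial_sequence()] table (or any data.frame with
#'   columns run, trial, stimulus, target).
#' @param params A [model_params()].
#' @param reset_between_runs Re-initialize values at each run start
#'   (default TRUE).
#' @return A `value_trace` data.frame: run, trial, stimulus, target, v,
#'   delta, v_updated.
#' @export
run_model <- function(seq, params, reset_between_runs = TRUE) {
  prep <- prep_sequence(seq, reset_between_runs)
  tr <- trace_values(prep, params$model_kind, params$alpha, params$omega,
                     params$v0)
  out <- data.frame(run = prep$run, trial = prep$trial,
                    stimulus = prep$stimulus, target = prep$R,
                    v = tr$v, delta = tr$delta, v_updated = tr$v_upd,
                    stringsAsFactors = FALSE)
  structure(out, params = params, reset_between_runs = reset_between_runs,
            class = c("value_trace", "data.frame"))
}

# Precompute the integer encodings the trial loop needs.
prep_sequence <- function(seq, reset_between_runs = TRUE) {
  if (nrow(seq) == 0) stop("empty trial sequence", call. = FALSE)
  ord <- order(seq$run, seq$trial)
  seq <- seq[ord, , drop = FALSE]
  assert_stimulus(seq$stimulus)
  n <- nrow(seq)
  list(si = match(seq$stimulus, stimulus_names()),
       R = seq$target,
       new_run = c(FALSE, seq$run[-1] != seq$run[-n]) & reset_between_runs,
       run = seq$run, trial = seq$trial, stimulus = seq$stimulus, n = n)
}

# Sequential delta-rule pass over a prepared sequence; the tight loop
# behind run_model and the model-fitting objective.
trace_values <- function(prep, kind, a, w, v0) {
  stim_names <- stimulus_names()
  n <- prep$n; si <- prep$si; R <- prep$R; new_run <- prep$new_run
  v <- numeric(n); delta <- numeric(n); v_upd <- numeric(n)

  if (kind == "no_learning") {
    delta <- R - 0
  } else if (kind == "base_rate") {
    val <- v0
    for (t in seq_len(n)) {
      if (new_run[t]) val <- v0
      v[t] <- val
      delta[t] <- R[t] - val
      val <- val + a * delta[t]
      v_upd[t] <- val
    }
  } else if (kind == "feature") {
    # feature membership of each stimulus, as indices into (A, B, C)
    fmem <- lapply(stim_names, function(s)
      match(stimulus_features()[[s]], c("A", "B", "C")))
    vals <- rep(v0, 3)
    for (t in seq_len(n)) {
      if (new_run[t]) vals <- rep(v0, 3)
      f <- fmem[[si[t]]]
      v[t] <- sum(vals[f])
      delta[t] <- R[t] - v[t]
      vals[f] <- vals[f] + a * delta[t]
      v_upd[t] <- sum(vals[f])
    }
  } else {
    # conjunctive / value_spread over per-stimulus values
    spread_to <- lapply(stim_names, function(s1)
      which(vapply(stim_names, function(s2)
        feature_overlap(s1, s2) == 1L, logical(1))))
    vals <- rep(v0, 4)
    for (t in seq_len(n)) {
      if (new_run[t]) vals <- rep(v0, 4)
      s <- si[t]
      v[t] <- vals[s]
      delta[t] <- R[t] - vals[s]
      vals[s] <- vals[s] + a * delta[t]
      if (kind == "value_spread" && w > 0) {
        sp <- spread_to[[s]]
        vals[sp] <- vals[sp] + a * delta[t] * w
      }
      v_upd[t] <- vals[s]
    }
  }
  list(v = v, delta = delta, v_upd = v_upd)
}

#' Write a value/prediction-error trace as TSV
#' @param trace A `value_trace` from [run_model()].
#' @param path Output path.
#' @export
write_value_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
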