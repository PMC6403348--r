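#' z-score a vector
#'
#' Centers and scales to unit SD. Errors on (numerically) constant input,
#' because a zero-variance regressor carries no information and would
#' silently produce NaNs.
#'
#' @param x Numeric vector.
#' @return z-scored vector.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    stop("cannot z-score a zero-variance vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Build feature and conjunctive prediction-error regressors
#'
#' Runs the feature and conjunctive learning models over a trial sequence
#' and constructs two z-scored trial-wise regressors: the feature-model
#' prediction error, and a difference regressor isolating the variance that
#' conjunctive learning explains over and above feature learning. With the
#' default `sign = "feature_minus_conj"` the difference is
#' `delta_feature - delta_conjunctive`; the alternative convention flips its
#' global sign. The convention and the parameters used are stamped on the
#' result, because downstream coefficient signs depend on them.
#'
#' @param seq A trial sequence.
#' @param feature_params [model_params()] for the feature model.
#' @param conj_params [model_params()] for the conjunctive model.
#' @param sign Difference convention, `"feature_minus_conj"` (default) or
#'   `"conj_minus_feature"`.
#' @param reset_between_runs Passed to [run_model()].
#' @return A `pe_regressors` data.frame: run, trial, target, z_feature_pe,
#'   z_conj_diff; attributes record the sign convention and parameters.
#' @export
build_pe_regressors <- function(seq, feature_params, conj_params,
                                sign = c("feature_minus_conj",
                                         "conj_minus_feature"),
                                reset_between_runs = TRUE) {
  sign <- match.arg(sign)
  if (feature_params$model_kind != "feature") {
    stop("feature_params must be a feature model", call. = FALSE)
  }
  if (conj_params$model_kind != "conjunctive") {
    stop("conj_params must be a conjunctive model", call. = FALSE)
  }
  tr_f <- run_model(seq, feature_params, reset_between_runs)
  tr_c <- run_model(seq, conj_params, reset_between_runs)
  diff_raw <- if (sign == "feature_minus_conj") tr_f$delta - tr_c$delta else
    tr_c$delta - tr_f$delta
  if (stats::sd(tr_f$delta) < 1e-12) {
    stop("feature prediction-error trace has zero variance", call. = FALSE)
  }
  if (stats::sd(diff_raw) < 1e-12) {
    stop("difference regressor has zero variance (identical model traces)",
         call. = FALSE)
  }
  out <- data.frame(run = tr_f$run, trial = tr_f$trial,
                    target = tr_f$target,
                    z_feature_pe = zscore(tr_f$delta),
                    z_conj_diff = zscore(diff_raw))
  structure(out, sign_convention = sign,
            feature_params = feature_params, conj_params = conj_params,
            class = c("pe_regressors", "data.frame"))
}

#' Two-stage regression of striatal activation estimates on outcome and
#' prediction-error regressors
#'
#' First stage: per-subject ordinary least squares of the per-trial
#' activation estimates on (intercept, target, feature PE, conjunctive
#' difference PE). Second stage: one-sample t-tests of the per-subject
#' coefficients against zero. For balanced designs this is equivalent to a
#' random-intercept mixed model for the group-level inference. Subjects
#' whose design is rank deficient are excluded and listed in `dropped`.
#'
#' @param betas Numeric vector of per-trial activation estimates, stacked
#'   across subjects.
#' @param regs A [build_pe_regressors()] set for one subject's sequence;
#'   recycled across subjects (the task sequence is identical for all).
#' @param subject_ids Vector of subject identifiers aligned with `betas`.
#' @return List: `coefficients` (group means), `t`, `p`, `df`,
#'   `per_subject` (subjects x coefficients matrix), `dropped`.
#' @export
striatal_beta_regression <- function(betas, regs, subject_ids) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  X1 <- cbind(intercept = 1, target = regs$target,
              z_feature_pe = regs$z_feature_pe,
              z_conj_diff = regs$z_conj_diff)
  coefs <- matrix(NA_real_, length(subjects), ncol(X1),
                  dimnames = list(subjects, colnames(X1)))
  dropped <- character(0)
  for (s in subjects) {
    y <- betas[subject_ids == s]
    if (length(y) != nrow(X1)) {
      stop("subject ", s, ": betas not aligned with regressors",
           call. = FALSE)
    }
    qrx <- qr(X1)
    if (qrx$rank < ncol(X1)) {
      dropped <- c(dropped, s)
      next
    }
    coefs[as.character(s), ] <- qr.coef(qrx, y)
  }
  ok <- stats::complete.cases(coefs)
  if (sum(ok) < 2) stop("fewer than 2 subjects with full-rank designs",
                        call. = FALSE)
  cc <- coefs[ok, , drop = FALSE]
  se <- apply(cc, 2, stats::sd) / sqrt(nrow(cc))
  tstat <- colMeans(cc) / se
  tstat[se < 1e-12] <- sign(colMeans(cc)[se < 1e-12]) * Inf
  df <- nrow(cc) - 1
  list(coefficients = colMeans(cc), t = tstat,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       df = df, per_subject = cc, dropped = dropped)
}

#' Run-level brain-behavior coupling
#'
#' Tests whether runs in which a region's pattern overlap is stronger are
#' also runs in which the striatal conjunctive prediction-error response is
#' weaker. Both run-level coefficients are centered within subject, a slope
#' of the conjunctive-PE coefficient on the overlap coefficient is estimated
#' per subject across runs, and the subject slopes are tested against zero
#' with a one-sample t-test (a two-stage analog of a random-slope model).
#' With only a few runs per subject the unweighted subject slopes are
#' heavy-tailed (a subject whose runs happen to have similar overlap
#' coefficients yields a wild slope), so the reported point estimate
#' `slope` is the precision-weighted (pooled within-subject) slope, with
#' the unweighted mean kept as `slope_unweighted`. Subjects with fewer
#' than two usable runs or a constant predictor after centering contribute
#' nothing and are listed in `dropped`.
#'
#' @param overlap_beta,conj_beta Numeric vectors of run-level coefficients.
#' @param subject_ids Subject identifier per entry.
#' @return List: `slope` (precision-weighted), `slope_unweighted`, `t`,
#'   `p`, `df` (from the one-sample t-test on subject slopes),
#'   `per_subject_slopes`, `dropped`.
#' @export
brain_behavior_coupling <- function(overlap_beta, conj_beta, subject_ids) {
  if (length(overlap_beta) != length(conj_beta) ||
      length(overlap_beta) != length(subject_ids)) {
    stop("inputs must be aligned", call. = FALSE)
  }
  subjects <- unique(subject_ids)
  slopes <- rep(NA_real_, length(subjects))
  weights <- rep(NA_real_, length(subjects))
  names(slopes) <- names(weights) <- subjects
  dropped <- character(0)
  for (s in subjects) {
    idx <- subject_ids == s
    x <- overlap_beta[idx] - mean(overlap_beta[idx])
    y <- conj_beta[idx] - mean(conj_beta[idx])
    if (sum(idx) < 2 || stats::sd(x) < 1e-12) {
      dropped <- c(dropped, as.character(s))
      next
    }
    slopes[as.character(s)] <- sum(x * y) / sum(x^2)
    weights[as.character(s)] <- sum(x^2)
  }
  ok <- !is.na(slopes)
  sl <- slopes[ok]
  if (length(sl) < 2) stop("fewer than 2 subjects with usable runs",
                           call. = FALSE)
  se <- stats::sd(sl) / sqrt(length(sl))
  tstat <- mean(sl) / se
  df <- length(sl) - 1
  list(slope = sum(weights[ok] * sl) / sum(weights[ok]),
       slope_unweighted = mean(sl), t = tstat,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       df = df, per_subject_slopes = sl, dropped = dropped)
}
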