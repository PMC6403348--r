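#' Construct a pattern dataset
#'
#' A trials x units activation matrix with per-trial metadata, the input to
#' pattern-similarity and pattern-content analyses. Row order must match
#' the trial sequence (sorted by run then trial).
#'
#' @param x Numeric matrix, trials in rows, units (voxel-like measurement
#'   channels) in columns.
#' @param meta Data.frame with one row per trial: run, trial, stimulus,
#'   target (additional columns are kept).
#' @param region Region label (character scalar).
#' @return A `pattern_dataset` list.
#' @export
pattern_dataset <- function(x, meta, region = "region") {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("pattern matrix must be finite", call. = FALSE)
  if (ncol(x) < 2) stop("need at least 2 units", call. = FALSE)
  if (nrow(x) != nrow(meta)) stop("meta rows must match pattern rows",
                                  call. = FALSE)
  structure(list(x = x, meta = as.data.frame(meta), region = region),
            class = "pattern_dataset")
}

#' Trial-pair pattern similarity matrix
#'
#' Correlates every pair of trial patterns across units, clips the
#' correlations to |r| <= 1 - 1e-7 and Fisher-transforms them so they are
#' unbounded and approximately normal. Pairs involving a zero-variance
#' trial pattern (whose correlation is undefined) are flagged and excluded
#' from downstream regressions.
#'
#' @param patterns A [pattern_dataset()].
#' @return A `psm` data.frame with one row per unordered pair i < j (1-based
#'   trial indices in sequence order): columns `i`, `j`, `z` (Fisher z) and
#'   `ok` (FALSE for excluded pairs). Attributes: `region`, `n_trials`.
#' @export
compute_psm <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_dataset"))
  x <- patterns$x
  n <- nrow(x)
  if (n < 3) stop("need at least 3 trials", call. = FALSE)
  sds <- apply(x, 1, stats::sd)
  degenerate <- sds < 1e-12
  xt <- t(x)
  r <- suppressWarnings(stats::cor(xt))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  ut <- upper.tri(z)
  idx <- which(ut, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], z = z[ut],
                    ok = !(degenerate[idx[, 1]] | degenerate[idx[, 2]]))
  out$z[!out$ok] <- NA_real_
  structure(out, region = patterns$region, n_trials = n,
            class = c("psm", "data.frame"))
}

#' Trial-pair design matrix for pattern-similarity regression
#'
#' Builds the pair-level regressors used to model a pattern similarity
#' matrix:
#' * `within_stimulus`: 1 for repetitions of the identical stimulus, else 0.
#' * `overlap`: 1 for different stimuli sharing a feature, -1 for different
#'   stimuli sharing none, 0 for same-stimulus pairs.
#' * `pe_similarity`, `value_similarity`: negated absolute differences of the
#'   trial-wise prediction errors and updated values from `trace`, so that
#'   larger (less negative) numbers mean more similar learning variables and
#'   positive coefficients mean similarity coding.
#' * `response` (+1 same response class, -1 otherwise) and `target` (+1 both
#'   target, -1 both non-target, 0 mixed) nuisance terms.
#' * one same-run indicator per run (run-mean nuisance).
#' * `time_linear`, `time_quadratic`: elapsed time between the two trials
#'   (in trial steps) and its square; `time_x_within`: their interaction
#'   with within-stimulus similarity.
#' * optionally `value_x_epoch`: the value-similarity term interacted with
#'   an epoch code (+1 both trials in the late half of their run, -1 both
#'   early, 0 mixed), testing whether outcome-similarity coding changes
#'   over learning.
#' * optionally the overlap term is replaced by separate `share` /
#'   `no_share` indicator columns (visualization model).
#'
#' The value and PE columns are orthogonalized against the response and
#' target codings (plus an intercept) by least-squares residualization, so
#' shared variance is assigned to the outcome regressors; all columns are
#' then z-scored so coefficients are comparable.
#'
#' @param seq A trial sequence (sorted by run, trial).
#' @param trace A `value_trace` aligned with `seq` (required unless both
#'   value columns are disabled).
#' @param epoch_interaction Include the value x epoch column (default FALSE).
#' @param overlap_split Replace `overlap` with share/no-share indicator
#'   columns (default FALSE).
#' @param include_value Include value/PE similarity columns (default TRUE).
#' @return A `psa_design` matrix (pairs x regressors) with attributes
#'   `pairs` (i, j index data.frame), `n_trials`, `orthogonalized`.
#' @export
build_psa_design <- function(seq, trace = NULL, epoch_interaction = FALSE,
                             overlap_split = FALSE, include_value = TRUE) {
  seq <- seq[order(seq$run, seq$trial), , drop = FALSE]
  n <- nrow(seq)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]

  stim <- seq$stimulus; targ <- seq$target; run <- seq$run
  same_stim <- as.numeric(stim[i] == stim[j])
  ov_lookup <- outer(stimulus_names(), stimulus_names(), feature_overlap)
  dimnames(ov_lookup) <- list(stimulus_names(), stimulus_names())
  overlap <- ifelse(same_stim == 1, 0,
                    ifelse(ov_lookup[cbind(stim[i], stim[j])] == 1, 1, -1))
  response <- ifelse(targ[i] == targ[j], 1, -1)
  target_pair <- ifelse(targ[i] == 1 & targ[j] == 1, 1,
                        ifelse(targ[i] == 0 & targ[j] == 0, -1, 0))

  pos <- seq_len(n)
  tdist <- abs(pos[i] - pos[j])
  time_linear <- tdist
  time_quadratic <- tdist^2
  time_x_within <- tdist * same_stim

  runs <- sort(unique(run))
  run_cols <- sapply(runs, function(r) as.numeric(run[i] == r & run[j] == r))
  colnames(run_cols) <- paste0("run_mean_", runs)
  # with a single run the indicator is constant (absorbed by the intercept)
  run_cols <- run_cols[, apply(run_cols, 2, stats::sd) > 1e-12, drop = FALSE]

  cols <- list(within_stimulus = same_stim)
  if (overlap_split) {
    cols$share <- as.numeric(overlap == 1)
    cols$no_share <- as.numeric(overlap == -1)
  } else {
    cols$overlap <- overlap
  }

  if (include_value) {
    if (is.null(trace)) stop("value/PE columns need a value trace",
                             call. = FALSE)
    trace <- trace[order(trace$run, trace$trial), , drop = FALSE]
    if (nrow(trace) != n) stop("trace not aligned with sequence",
                               call. = FALSE)
    pe_sim <- -abs(trace$delta[i] - trace$delta[j])
    value_sim <- -abs(trace$v_updated[i] - trace$v_updated[j])
    nuis <- qr(cbind(1, response, target_pair))
    orth <- function(x) qr.resid(nuis, x)
    cols$pe_similarity <- orth(pe_sim)
    cols$value_similarity <- orth(value_sim)
    if (epoch_interaction) {
      half <- stats::ave(seq$trial, seq$run,
                         FUN = function(tr) tr >= stats::median(tr))
      epoch <- ifelse(half[i] == 1 & half[j] == 1, 1,
                      ifelse(half[i] == 0 & half[j] == 0, -1, 0))
      # the epoch main effect and its interaction with within-stimulus
      # similarity accompany the value x epoch term: without them, overall
      # late-versus-early similarity changes and the (dominant)
      # within-stimulus structure alias into it
      cols$epoch <- epoch
      cols$within_x_epoch <- same_stim * epoch
      # the value x epoch interaction is defined over between-stimulus
      # pairs (same-stimulus similarity is the within-stimulus effect, not
      # outcome-similarity coding); the value code is centered within the
      # both-early and both-late pair groups so the column carries only
      # the change in value-similarity slope, not epoch mean differences
      vcode <- ifelse(same_stim == 0, value_sim, NA_real_)
      ve <- numeric(length(epoch))
      for (ep in c(-1, 1)) {
        g_idx <- which(epoch == ep & !is.na(vcode))
        if (length(g_idx) > 1) {
          ve[g_idx] <- (vcode[g_idx] - mean(vcode[g_idx])) * ep
        }
      }
      cols$value_x_epoch <- ve
    }
  } else if (epoch_interaction) {
    stop("epoch interaction requires value columns", call. = FALSE)
  }

  cols$response <- response
  cols$target <- target_pair
  for (k in colnames(run_cols)) cols[[k]] <- run_cols[, k]
  cols$time_linear <- time_linear
  cols$time_quadratic <- time_quadratic
  cols$time_x_within <- time_x_within

  X <- do.call(cbind, lapply(cols, as.numeric))
  colnames(X) <- names(cols)
  X <- apply(X, 2, zscore)
  structure(X, pairs = data.frame(i = i, j = j), n_trials = n,
            orthogonalized = include_value,
            class = c("psa_design", "matrix"))
}

#' Ordinary least squares on a pattern similarity matrix
#'
#' Regresses the Fisher-z pair similarities on the design columns (plus an
#' intercept). Errors when the design is rank deficient, naming the
#' collinear columns.
#'
#' @param psm A [compute_psm()] result.
#' @param design A [build_psa_design()] matrix with rows matching the psm
#'   pairs.
#' @return Named coefficient vector (including `(Intercept)`).
#' @export
fit_psm_regression <- function(psm, design) {
  if (nrow(psm) != nrow(design)) {
    stop("design rows must match psm pairs", call. = FALSE)
  }
  keep <- psm$ok
  X <- cbind(`(Intercept)` = 1, design[keep, , drop = FALSE])
  y <- psm$z[keep]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(qr.coef(qrx, y)), colnames(X))
}

# Projection matrix mapping a similarity vector to OLS coefficients,
# computed once so permutation nulls reduce to matrix products.
psm_projection <- function(psm, design) {
  keep <- psm$ok
  X <- cbind(`(Intercept)` = 1, design[keep, , drop = FALSE])
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  R <- qr.R(qrx)
  Q <- qr.Q(qrx)
  P <- backsolve(R, t(Q))
  rownames(P) <- colnames(X)
  list(P = P, keep = keep)
}

#' One-sided permutation test of pattern-similarity coefficients
#'
#' Compares each observed regression coefficient with a null distribution
#' obtained by uniformly shuffling the vector of Fisher-z pair similarities
#' `n_perm` times and refitting the full model. The p-value is
#' `(1 + #(null >= observed)) / (1 + n_perm)` for a positive-signed
#' hypothesis; set `sign = -1` for columns where the hypothesized effect is
#' negative. An alternative `shuffle = "trials"` mode permutes trial labels
#' instead (a stricter exchangeability assumption that preserves the pair
#' structure of the similarity matrix).
#'
#' @param psm A [compute_psm()] result.
#' @param design A [build_psa_design()] matrix.
#' @param columns Character vector of design column names to test.
#' @param n_perm Number of shuffles (default 10000).
#' @param seed Integer seed.
#' @param sign Scalar or named vector of +1/-1 test directions per column.
#' @param shuffle `"values"` (default: shuffle pair similarities) or
#'   `"trials"` (permute trial labels).
#' @return Named list per column: `observed`, `p`, `null` (numeric vector
#'   of permuted coefficients).
#' @export
permutation_test <- function(psm, design, columns, n_perm = 10000, seed = 1,
                             sign = 1, shuffle = c("values", "trials")) {
  shuffle <- match.arg(shuffle)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (!all(columns %in% colnames(design))) {
    stop("unknown design columns: ",
         paste(setdiff(columns, colnames(design)), collapse = ", "),
         call. = FALSE)
  }
  signs <- if (length(sign) == 1) stats::setNames(rep(sign, length(columns)),
                                                  columns) else sign[columns]
  proj <- psm_projection(psm, design)
  y <- psm$z[proj$keep]
  obs <- as.numeric(proj$P %*% y)
  names(obs) <- rownames(proj$P)

  set.seed(as.integer(seed))
  m <- length(y)
  null_mat <- matrix(NA_real_, n_perm, length(columns),
                     dimnames = list(NULL, columns))
  if (shuffle == "values") {
    chunk <- 500L
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      Y <- vapply(seq_len(nb), function(b) y[sample.int(m)], numeric(m))
      B <- proj$P %*% Y
      null_mat[done + seq_len(nb), ] <- t(B[columns, , drop = FALSE])
      done <- done + nb
    }
  } else {
    n_tr <- attr(design, "n_trials")
    pairs <- attr(design, "pairs")
    key <- function(a, b) ifelse(a < b, (a - 1) * n_tr + b,
                                 (b - 1) * n_tr + a)
    row_of <- stats::setNames(seq_len(nrow(pairs)),
                              key(pairs$i, pairs$j))
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n_tr)
      new_rows <- row_of[as.character(key(perm[pairs$i], perm[pairs$j]))]
      yp <- psm$z[new_rows][proj$keep]
      if (any(is.na(yp))) next
      null_mat[b, ] <- as.numeric(proj$P[columns, , drop = FALSE] %*% yp)
    }
  }
  out <- lapply(columns, function(cn) {
    s <- signs[[cn]]
    nulls <- null_mat[, cn]
    nulls <- nulls[is.finite(nulls)]
    p <- (1 + sum(s * nulls >= s * obs[[cn]])) / (1 + length(nulls))
    list(observed = obs[[cn]], p = p, null = nulls)
  })
  stats::setNames(out, columns)
}

#' Permutation test of a coefficient difference between two regions
#'
#' Tests whether a design column's coefficient differs between two pattern
#' similarity matrices computed over the same trial pairs. The same random
#' shuffles of the pair-similarity vectors are applied to both regions and
#' the difference of coefficients is recomputed, giving a paired null; the
#' one-sided p-value is computed as in [permutation_test()].
#'
#' @param psm_a,psm_b `psm` objects over identical pair sets.
#' @param design Shared [build_psa_design()] matrix.
#' @param column Single design column name.
#' @param n_perm,seed As in [permutation_test()].
#' @param sign +1 to test a > b, -1 to test a < b.
#' @return List: `observed` (difference a - b), `p`, `null`.
#' @export
region_contrast <- function(psm_a, psm_b, design, column, n_perm = 10000,
                            seed = 1, sign = 1) {
  if (nrow(psm_a) != nrow(psm_b)) {
    stop("regions have mismatched pair sets", call. = FALSE)
  }
  ok <- psm_a$ok & psm_b$ok
  pa <- psm_a; pa$ok <- ok
  pb <- psm_b; pb$ok <- ok
  proj <- psm_projection(pa, design)
  ya <- pa$z[ok]; yb <- pb$z[ok]
  Pc <- proj$P[column, , drop = FALSE]
  obs <- as.numeric(Pc %*% ya) - as.numeric(Pc %*% yb)
  set.seed(as.integer(seed))
  m <- length(ya)
  nulls <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pa_i <- sample.int(m); pb_i <- sample.int(m)
    nulls[b] <- as.numeric(Pc %*% ya[pa_i]) - as.numeric(Pc %*% yb[pb_i])
  }
  p <- (1 + sum(sign * nulls >= sign * obs)) / (1 + n_perm)
  list(observed = obs, p = p, null = nulls)
}
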