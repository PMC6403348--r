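#' Task stimuli and their feature composition
#'
#' The task uses four compound stimuli built from three visual features A, B
#' and C: the two-feature stimuli AB and AC and the single-feature stimuli B
#' and C. AB and C predict the target with high probability, AC and B with
#' low probability, so that every individual feature predicts the target at
#' its base rate and only conjunctions carry predictive information.
#'
#' @return Named list mapping each stimulus name to its character vector of
#'   features.
#' @export
#' @examples
#' stimulus_features()
stimulus_features <- function() {
  list(AB = c("A", "B"), AC = c("A", "C"), B = "B", C = "C")
}

#' Names of the four task stimuli
#' @return Character vector `c("AB", "AC", "B", "C")`.
#' @export
stimulus_names <- function() names(stimulus_features())

assert_stimulus <- function(s) {
  bad <- !s %in% stimulus_names()
  if (any(bad)) {
    stop("unknown stimulus: ", paste(unique(s[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(s)
}

#' Feature overlap indicator between two stimuli
#'
#' Returns 1 when two *distinct* stimuli share at least one feature and 0
#' otherwise. A stimulus does not overlap with itself: the indicator feeds
#' the value-spread update, which only spreads to other stimuli. The
#' overlapping pairs are (AB, AC), (AB, B) and (AC, C); the non-overlapping
#' pairs are (AB, C), (AC, B) and (B, C).
#'
#' @param s1,s2 Stimulus names (vectorized, recycled to common length).
#' @return Integer vector of 0/1 indicators.
#' @export
#' @examples
#' feature_overlap("AB", "AC")  # share A -> 1
#' feature_overlap("B", "C")    # -> 0
feature_overlap <- function(s1, s2) {
  assert_stimulus(s1); assert_stimulus(s2)
  n <- max(length(s1), length(s2))
  s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  feats <- stimulus_features()
  out <- integer(n)
  for (i in seq_len(n)) {
    if (s1[i] != s2[i] &&
        length(intersect(feats[[s1[i]]], feats[[s2[i]]])) > 0L) {
      out[i] <- 1L
    }
  }
  out
}

#' Generate a pseudo-random trial sequence for the task
#'
#' Builds `n_runs` runs each containing `trials_per_stimulus` trials of each
#' of the four stimuli in shuffled order. AB and C predict the target with
#' probability `p_high`; AC and B with probability `p_low`. In `"exact"` mode
#' (the default) the number of target trials per stimulus per run is exactly
#' `round(p * trials_per_stimulus)`, so the designed contingencies hold
#' within every run; in `"bernoulli"` mode each trial's target is an
#' independent draw.
#'
#' @param n_runs Number of runs (default 3).
#' @param trials_per_stimulus Trials per stimulus per run (default 10).
#' @param p_high,p_low Target probabilities for the high (AB, C) and low
#'   (AC, B) contingency stimuli. Defaults 0.7 and 0.3.
#' @param mode `"exact"` or `"bernoulli"`.
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @param strict In exact mode, error when `p * trials_per_stimulus` is not
#'   an integer (default TRUE). When FALSE the count is rounded.
#' @return A `trial_sequence`: a data.frame with columns `run`, `trial`
#'   (both 0-based), `stimulus` and `target`, with the generation parameters
#'   stored as attributes.
#' @export
#' @examples
#' seq <- make_trial_sequence(seed = 1)
#' table(seq$run, seq$stimulus)
make_trial_sequence <- function(n_runs = 3, trials_per_stimulus = 10,
                                p_high = 0.7, p_low = 0.3,
                                mode = c("exact", "bernoulli"),
                                seed = 1L, strict = TRUE) {
  mode <- match.arg(mode)
  if (n_runs < 1 || trials_per_stimulus < 1) {
    stop("n_runs and trials_per_stimulus must be positive", call. = FALSE)
  }
  if (!(p_low >= 0 && p_high <= 1 && p_low <= p_high)) {
    stop("need 0 <= p_low <= p_high <= 1", call. = FALSE)
  }
  p_of <- c(AB = p_high, AC = p_low, B = p_low, C = p_high)
  if (mode == "exact" && strict) {
    for (p in c(p_high, p_low)) {
      if (abs(p * trials_per_stimulus - round(p * trials_per_stimulus)) > 1e-8) {
        stop("p * trials_per_stimulus = ", p * trials_per_stimulus,
             " is not an integer; use strict = FALSE or bernoulli mode",
             call. = FALSE)
      }
    }
  }
  set.seed(as.integer(seed))
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    stim <- rep(stimulus_names(), each = trials_per_stimulus)
    targ <- integer(length(stim))
    for (s in stimulus_names()) {
      idx <- which(stim == s)
      if (mode == "exact") {
        k <- as.integer(round(p_of[[s]] * trials_per_stimulus))
        targ[sample(idx, k)] <- 1L
      } else {
        targ[idx] <- stats::rbinom(length(idx), 1L, p_of[[s]])
      }
    }
    ord <- sample.int(length(stim))
    runs[[r]] <- data.frame(
      run = r - 1L,
      trial = seq_along(stim) - 1L,
      stimulus = stim[ord],
      target = targ[ord],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  structure(out,
            n_runs = n_runs, trials_per_stimulus = trials_per_stimulus,
            p_high = p_high, p_low = p_low, mode = mode, seed = seed,
            class = c("trial_sequence", "data.frame"))
}

#' Write / read a trial sequence as TSV with a JSON sidecar
#'
#' The trial table is written as tab-separated text (columns run, trial,
#' stimulus, target); generation parameters and the seed go into
#' `<path>.json` so sequences are fully reproducible from disk.
#'
#' @param seq A `trial_sequence`.
#' @param path File path for the TSV.
#' @return `write_trial_sequence` returns `path` invisibly;
#'   `read_trial_sequence` returns a `trial_sequence`.
#' @export
write_trial_sequence <- function(seq, path) {
  utils::write.table(as.data.frame(seq), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- attributes(seq)[c("n_runs", "trials_per_stimulus", "p_high",
                            "p_low", "mode", "seed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trial_sequence
#' @export
read_trial_sequence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("run", "trial", "stimulus", "target")
  if (!all(need %in% names(df))) {
    stop("trial table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  assert_stimulus(df$stimulus)
  if (!all(df$target %in% c(0L, 1L))) stop("target must be 0/1", call. = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(df,
            n_runs = length(unique(df$run)),
            trials_per_stimulus = meta$trials_per_stimulus,
            p_high = meta$p_high, p_low = meta$p_low,
            mode = meta$mode, seed = meta$seed,
            class = c("trial_sequence", "data.frame"))
}
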