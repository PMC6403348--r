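#' Configuration for the behavior generator
#'
#' Defaults encode the study conditions the analyses assume: value-spread
#' learning with learning rate 0.3 and spread 0.44, a log reaction-time
#' model with intercept log(0.4 s) and value slope -0.4 (faster responses to
#' higher-valued stimuli), residual SD 0.15 log-units, a response threshold
#' calibrated in 30 ms steps before the task and tracked in 10 ms steps
#' during it, and a logistic anticipation rule mapping value to the
#' probability of responding before any target appears.
#'
#' @param params Generating [model_params()].
#' @param rt_intercept Mean log RT (log seconds) at value 0.
#' @param value_slope Change in mean log RT per unit value (negative:
#'   higher value, faster response).
#' @param rt_noise_sd Residual SD of log RT.
#' @param threshold_init Starting response threshold in seconds.
#' @param threshold_step_calibration Calibration-phase step (seconds).
#' @param threshold_step_task Task-phase step (seconds).
#' @param n_calibration Number of calibration trials before the task.
#' @param anticipation `c(intercept, slope)` of the logistic rule
#'   `P(respond | no target) = plogis(intercept + slope * value)`.
#' @param seed Integer seed.
#' @return A `behavior_config` list.
#' @export
behavior_config <- function(params = model_params("value_spread",
                                                  alpha = 0.3, omega = 0.44),
                            rt_intercept = log(0.4), value_slope = -0.4,
                            rt_noise_sd = 0.15,
                            threshold_init = 0.4,
                            threshold_step_calibration = 0.030,
                            threshold_step_task = 0.010,
                            n_calibration = 60,
                            anticipation = c(-2, 3),
                            seed = 1L) {
  if (rt_noise_sd < 0) stop("rt_noise_sd must be >= 0", call. = FALSE)
  if (threshold_step_calibration <= 0 || threshold_step_task <= 0) {
    stop("threshold steps must be positive", call. = FALSE)
  }
  structure(list(params = params, rt_intercept = rt_intercept,
                 value_slope = value_slope, rt_noise_sd = rt_noise_sd,
                 threshold_init = threshold_init,
                 threshold_step_calibration = threshold_step_calibration,
                 threshold_step_task = threshold_step_task,
                 n_calibration = n_calibration,
                 anticipation = anticipation, seed = seed),
            class = "behavior_config")
}

#' Simulate task behavior from a learning model
#'
#' Runs the generating model over the trial sequence and produces, per
#' trial, a latent log reaction time
#' `rt_intercept + value_slope * v_t + Normal(0, rt_noise_sd)`. On target
#' trials the subject always responds and earns a reward (hit) when the
#' reaction time beats the current threshold; on non-target trials the
#' subject responds (a false alarm, losing money) with the logistic
#' anticipation probability. The threshold starts from a calibration phase
#' of value-free trials adjusted in 30 ms steps toward 50% success and then
#' tracks performance in 10 ms steps during the task, so a non-learning
#' subject hits on about half of target trials.
#'
#' @param seq A [make_trial_sequence()] table.
#' @param cfg A [behavior_config()].
#' @return Data.frame with one row per trial: run, trial, stimulus, target,
#'   v_true, responded, rt (s; NA if no response), log_rt, hit,
#'   false_alarm, outcome (hit/miss/false_alarm/correct_rejection), reward
#'   (dollars), threshold (s, value at the trial). Attribute `config`.
#' @export
simulate_behavior <- function(seq, cfg = behavior_config()) {
  stopifnot(inherits(cfg, "behavior_config"))
  seq <- seq[order(seq$run, seq$trial), , drop = FALSE]
  trace <- run_model(seq, cfg$params)
  set.seed(as.integer(cfg$seed))
  thr <- cfg$threshold_init
  for (k in seq_len(cfg$n_calibration)) {
    rt <- exp(cfg$rt_intercept + stats::rnorm(1, 0, cfg$rt_noise_sd))
    thr <- thr + if (rt <= thr) -cfg$threshold_step_calibration else
      cfg$threshold_step_calibration
    thr <- max(thr, 0.05)
  }
  n <- nrow(seq)
  v <- trace$v
  rt <- rep(NA_real_, n); responded <- logical(n)
  hit <- logical(n); fa <- logical(n)
  reward <- numeric(n); outcome <- character(n); thr_trace <- numeric(n)
  p_ant <- stats::plogis(cfg$anticipation[1] + cfg$anticipation[2] * v)
  for (t in seq_len(n)) {
    thr_trace[t] <- thr
    latent_rt <- exp(cfg$rt_intercept + cfg$value_slope * v[t] +
                       stats::rnorm(1, 0, cfg$rt_noise_sd))
    if (seq$target[t] == 1) {
      responded[t] <- TRUE
      rt[t] <- latent_rt
      if (latent_rt <= thr) {
        hit[t] <- TRUE; reward[t] <- 0.25; outcome[t] <- "hit"
      } else {
        outcome[t] <- "miss"
      }
      thr <- thr + if (latent_rt <= thr) -cfg$threshold_step_task else
        cfg$threshold_step_task
      thr <- max(thr, 0.05)
    } else {
      if (stats::runif(1) < p_ant[t]) {
        responded[t] <- TRUE
        rt[t] <- latent_rt
        fa[t] <- TRUE; reward[t] <- -0.25; outcome[t] <- "false_alarm"
      } else {
        outcome[t] <- "correct_rejection"
      }
    }
  }
  out <- data.frame(run = seq$run, trial = seq$trial,
                    stimulus = seq$stimulus, target = seq$target,
                    v_true = v,
                    responded = as.integer(responded), rt = rt,
                    log_rt = log(rt), hit = as.integer(hit),
                    false_alarm = as.integer(fa), outcome = outcome,
                    reward = reward, threshold = thr_trace,
                    stringsAsFactors = FALSE)
  structure(out, config = cfg,
            class = c("behavioral_dataset", "data.frame"))
}

#' Configuration for the multivoxel-like pattern generator
#'
#' Generative knobs for the representational structure the pattern analyses
#' probe: per-stimulus prototype strength (`within_strength`, pattern
#' stability), shared feature-component strength (`overlap_strength`),
#' value-axis coding (`value_slope`) with an optional learning-related
#' repulsion (`epoch_mod`: positive values rotate each stimulus's value
#' coding into stimulus-specific directions over the run, anti-aligning
#' the equal-valued pairs, so same-valued stimuli drift apart in pattern
#' space late in learning; values up to ~2 complete the rotation by
#' mid-run), unit noise, and the
#' representational `mode`: `"additive"` builds two-feature patterns as the
#' sum of their feature components (the sensory-cortex hypothesis) while
#' `"conjunctive"` gives two-feature stimuli their own prototypes orthogonal
#' to the feature components (the pattern-separated hippocampal hypothesis).
#'
#' @param n_units Number of measurement units (>= 10, default 60).
#' @param within_strength Prototype weight a (default 1).
#' @param overlap_strength Feature-component weight b (default 0.8).
#' @param value_slope Value-axis weight c (default 0.5).
#' @param epoch_mod Epoch modulation d of value coding (default 0).
#' @param noise_sd Unit noise SD (default 0.2).
#' @param mode `"additive"` or `"conjunctive"`.
#' @param region Region label for the generated dataset.
#' @param seed Integer seed.
#' @return A `pattern_config` list.
#' @export
pattern_config <- function(n_units = 60, within_strength = 1,
                           overlap_strength = 0.8, value_slope = 0.5,
                           epoch_mod = 0, noise_sd = 0.2,
                           mode = c("additive", "conjunctive"),
                           region = "region", seed = 1L) {
  mode <- match.arg(mode)
  if (n_units < 10) stop("n_units must be >= 10", call. = FALSE)
  structure(list(n_units = n_units, within_strength = within_strength,
                 overlap_strength = overlap_strength,
                 value_slope = value_slope, epoch_mod = epoch_mod,
                 noise_sd = noise_sd, mode = mode, region = region,
                 seed = seed),
            class = "pattern_config")
}

#' Fixed orthonormal pattern basis shared across generators
#'
#' Draws one unit-norm, mutually orthogonal axis per stimulus prototype,
#' per localizer category and for the value dimension, so task patterns and
#' localizer templates interlock: the feature component of a task pattern
#' is the prototype of the category playing that feature in that run.
#'
#' @param n_units Number of units.
#' @param categories Localizer category names (default face, house,
#'   bodypart).
#' @param seed Integer seed.
#' @return List: `stimulus` (4 x n_units), `category`
#'   (categories x n_units), `value_axis` and `value_ortho` (length
#'   n_units; the 2-D subspace carrying value coding).
#' @export
make_pattern_basis <- function(n_units = 60,
                               categories = c("face", "house", "bodypart"),
                               seed = 1L) {
  k <- 4 + length(categories) + 2
  if (n_units < k) stop("n_units too small for an orthonormal basis",
                        call. = FALSE)
  set.seed(as.integer(seed))
  M <- matrix(stats::rnorm(n_units * k), n_units, k)
  Q <- qr.Q(qr(M))
  stim <- t(Q[, 1:4]); rownames(stim) <- stimulus_names()
  cat <- t(Q[, 4 + seq_along(categories)]); rownames(cat) <- categories
  list(stimulus = stim, category = cat,
       value_axis = Q[, k - 1], value_ortho = Q[, k])
}

#' Simulate per-trial multivoxel-like patterns
#'
#' Generates `pattern_t = a * prototype(stimulus) + b * sum(feature
#' components) + c * (1 + d * e_t) * v_t * value_axis + noise`, where the
#' feature components are the localizer-category prototypes mapped to the
#' trial's features in its run and `e_t` is the trial's position within its
#' run scaled to \[-1, 1\]. In `"conjunctive"` mode two-feature stimuli
#' carry only their own prototype (no feature components); in `"additive"`
#' mode they carry only the sum of their feature components. Single-feature
#' stimuli always carry both their prototype and their feature component.
#'
#' @param seq A trial sequence.
#' @param trace A `value_trace` aligned with `seq` (its `v_updated` column
#'   drives value coding).
#' @param cfg A [pattern_config()].
#' @param basis A [make_pattern_basis()] result (created from `cfg$seed`
#'   when NULL).
#' @param mapping Feature-to-category mapping (default counterbalanced via
#'   [make_feature_category_mapping()]).
#' @return A [pattern_dataset()].
#' @export
simulate_patterns <- function(seq, trace, cfg = pattern_config(),
                              basis = NULL, mapping = NULL) {
  stopifnot(inherits(cfg, "pattern_config"))
  seq <- seq[order(seq$run, seq$trial), , drop = FALSE]
  trace <- trace[order(trace$run, trace$trial), , drop = FALSE]
  if (nrow(trace) != nrow(seq)) stop("trace not aligned with sequence",
                                     call. = FALSE)
  if (is.null(basis)) basis <- make_pattern_basis(cfg$n_units,
                                                  seed = cfg$seed)
  if (is.null(mapping)) {
    mapping <- make_feature_category_mapping(length(unique(seq$run)),
                                             rownames(basis$category))
  }
  set.seed(as.integer(cfg$seed) + 1L)
  n <- nrow(seq)
  feats <- stimulus_features()
  x <- matrix(stats::rnorm(n * cfg$n_units, 0, cfg$noise_sd), n,
              cfg$n_units)
  pos_in_run <- stats::ave(seq$trial, seq$run, FUN = function(tr) {
    if (length(tr) == 1) 0 else 2 * (rank(tr) - 1) / (length(tr) - 1) - 1
  })
  for (t in seq_len(n)) {
    s <- seq$stimulus[t]
    two <- length(feats[[s]]) == 2
    signal <- numeric(cfg$n_units)
    use_proto <- !two || cfg$mode == "conjunctive"
    use_comps <- !two || cfg$mode == "additive"
    if (use_proto) {
      signal <- signal + cfg$within_strength * basis$stimulus[s, ]
    }
    if (use_comps && cfg$overlap_strength != 0) {
      for (f in feats[[s]]) {
        cat_f <- map_category(mapping, seq$run[t], f)
        signal <- signal + cfg$overlap_strength * basis$category[cat_f, ]
      }
    }
    # value coding starts on a shared axis; when epoch_mod > 0 it rotates
    # over the run into stimulus-specific directions of a 2-D value
    # subspace, arranged so the equal-valued stimulus pairs (AB vs C,
    # AC vs B) end up anti-aligned: representations of stimuli with
    # similar target associations drift apart as learning proceeds
    # (norm-preserving)
    u <- (pos_in_run[t] + 1) / 2
    m <- min(max(cfg$epoch_mod * u, 0), 1)
    ang <- m * c(AB = 0, AC = pi / 2, B = 3 * pi / 2, C = pi)[[s]]
    signal <- signal + cfg$value_slope * trace$v_updated[t] *
      (cos(ang) * basis$value_axis + sin(ang) * basis$value_ortho)
    x[t, ] <- x[t, ] + signal
  }
  pattern_dataset(x, seq[, c("run", "trial", "stimulus", "target")],
                  region = cfg$region)
}

#' Simulate per-trial striatal activation estimates
#'
#' Builds `beta_t = w_target * target_t + w_feature * z_feature_pe_t +
#' w_conj * z_conj_diff_t + Normal(0, noise_sd)`, the generative twin of the
#' striatal decomposition analysis.
#'
#' @param regs A [build_pe_regressors()] set.
#' @param weights Named list/vector with `w_target`, `w_feature`, `w_conj`.
#' @param noise_sd Noise SD.
#' @param seed Integer seed.
#' @return Numeric vector of per-trial activation estimates.
#' @export
simulate_striatal_betas <- function(regs, weights = c(w_target = 2,
                                                      w_feature = 1,
                                                      w_conj = 0.5),
                                    noise_sd = 1, seed = 1L) {
  set.seed(as.integer(seed))
  weights[["w_target"]] * regs$target +
    weights[["w_feature"]] * regs$z_feature_pe +
    weights[["w_conj"]] * regs$z_conj_diff +
    stats::rnorm(nrow(regs), 0, noise_sd)
}

#' Simulate localizer blocks
#'
#' Each block is its category's basis prototype plus unit noise, so
#' [build_templates()] recovers (noisy copies of) the same prototypes that
#' [simulate_patterns()] uses as feature components.
#'
#' @param categories Category names (>= 2).
#' @param blocks_per_category Blocks per category (default 6).
#' @param cfg A [pattern_config()] (n_units, noise_sd and region are used).
#' @param basis Shared [make_pattern_basis()]; created from `cfg$seed` when
#'   NULL.
#' @param seed Integer seed for the block noise.
#' @return A [pattern_dataset()] whose meta has a `category` column.
#' @export
simulate_localizer <- function(categories = c("face", "house", "bodypart"),
                               blocks_per_category = 6,
                               cfg = pattern_config(), basis = NULL,
                               seed = 1L) {
  if (length(categories) < 2) stop("need at least 2 categories",
                                   call. = FALSE)
  if (is.null(basis)) basis <- make_pattern_basis(cfg$n_units,
                                                  categories = categories,
                                                  seed = cfg$seed)
  if (!all(categories %in% rownames(basis$category))) {
    stop("basis lacks some requested categories", call. = FALSE)
  }
  set.seed(as.integer(seed))
  lab <- rep(categories, each = blocks_per_category)
  x <- t(vapply(lab, function(cc) {
    basis$category[cc, ] + stats::rnorm(cfg$n_units, 0, cfg$noise_sd)
  }, numeric(cfg$n_units)))
  meta <- data.frame(run = 0L, trial = seq_along(lab) - 1L,
                     category = lab, stringsAsFactors = FALSE)
  pattern_dataset(x, meta, region = paste0(cfg$region, "_localizer"))
}
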