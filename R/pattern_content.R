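#' Build category templates from localizer blocks
#'
#' Computes, for each stimulus category, the arithmetic mean pattern across
#' its localizer blocks. Templates whose pattern is (numerically) constant
#' are flagged as degenerate because a correlation with them is undefined.
#'
#' @param localizer A [pattern_dataset()] whose `meta` has a `category`
#'   column labelling every block.
#' @return A `template_set` list: `templates` (categories x units matrix),
#'   `n_blocks` (blocks averaged per category), `degenerate` (logical per
#'   category).
#' @export
build_templates <- function(localizer) {
  stopifnot(inherits(localizer, "pattern_dataset"))
  labels <- localizer$meta$category
  if (is.null(labels)) stop("localizer meta needs a 'category' column",
                            call. = FALSE)
  cats <- unique(labels)
  if (any(table(labels) < 1)) stop("every category needs at least one block",
                                   call. = FALSE)
  tpl <- t(sapply(cats, function(cc) {
    colMeans(localizer$x[labels == cc, , drop = FALSE])
  }))
  rownames(tpl) <- cats
  degen <- apply(tpl, 1, stats::sd) < 1e-12
  structure(list(templates = tpl,
                 n_blocks = stats::setNames(as.integer(table(labels)[cats]),
                                            cats),
                 degenerate = degen),
            class = "template_set")
}

#' Run-specific feature-to-category mapping
#'
#' The visual category (e.g., face, house, body part) playing each feature
#' role rotates across runs. This helper builds the default counterbalanced
#' (cyclic) mapping assigning a category to features A, B and C in each run.
#'
#' @param n_runs Number of runs.
#' @param categories Character vector of at least 3 category names.
#' @param counterbalance Rotate the assignment across runs (default TRUE).
#' @return Data.frame: run, feature, category.
#' @export
make_feature_category_mapping <- function(n_runs = 3,
                                          categories = c("face", "house",
                                                         "bodypart"),
                                          counterbalance = TRUE) {
  if (length(categories) < 3) stop("need at least 3 categories",
                                   call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_runs) - 1L, function(r) {
    shift <- if (counterbalance) r %% 3L else 0L
    data.frame(run = r, feature = c("A", "B", "C"),
               category = categories[((seq_len(3) - 1L + shift) %% 3L) + 1L],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

map_category <- function(mapping, run, feature) {
  hit <- mapping$run == run & mapping$feature == feature
  if (sum(hit) != 1) stop("no unique mapping for feature ", feature,
                          " in run ", run, call. = FALSE)
  mapping$category[hit]
}

#' Task-to-template pattern similarity by condition
#'
#' Correlates each task trial's pattern with the localizer template of the
#' category mapped to its diagnostic feature in that run: B and AB trials
#' are scored against B's category template, C and AC trials against C's.
#' Because a single-feature stimulus and its two-feature counterpart are
#' always scored against the same template within a run, the single- versus
#' two-feature contrast reflects differences in the task representations
#' only. Correlations are clipped and Fisher-transformed as in
#' [compute_psm()].
#'
#' @param task A [pattern_dataset()] of task trials.
#' @param templates A [build_templates()] result.
#' @param mapping A [make_feature_category_mapping()]-style data.frame.
#' @return A `content_result` list: `per_trial` (run, trial, stimulus,
#'   condition, category, z), `per_run` (mean z per run x condition),
#'   `condition_means`, `region`.
#' @export
template_similarity <- function(task, templates, mapping) {
  stopifnot(inherits(task, "pattern_dataset"),
            inherits(templates, "template_set"))
  meta <- task$meta
  n <- nrow(task$x)
  feat_of <- c(AB = "B", B = "B", AC = "C", C = "C")
  cond_of <- c(AB = "two_feature", AC = "two_feature",
               B = "single_feature", C = "single_feature")
  z <- numeric(n); cat_used <- character(n)
  for (t in seq_len(n)) {
    cat_t <- map_category(mapping, meta$run[t], feat_of[[meta$stimulus[t]]])
    if (!cat_t %in% rownames(templates$templates)) {
      stop("no template for category '", cat_t, "'", call. = FALSE)
    }
    if (templates$degenerate[[cat_t]]) {
      stop("template for category '", cat_t, "' is degenerate",
           call. = FALSE)
    }
    r <- stats::cor(task$x[t, ], templates$templates[cat_t, ])
    r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
    z[t] <- atanh(r)
    cat_used[t] <- cat_t
  }
  per_trial <- data.frame(run = meta$run, trial = meta$trial,
                          stimulus = meta$stimulus,
                          condition = unname(cond_of[meta$stimulus]),
                          category = cat_used, z = z,
                          stringsAsFactors = FALSE)
  agg <- stats::aggregate(z ~ run + condition, per_trial, mean)
  cond_means <- tapply(agg$z, agg$condition, mean)
  structure(list(per_trial = per_trial, per_run = agg,
                 condition_means = cond_means, region = task$region),
            class = "content_result")
}

#' Permutation contrasts for the pattern-content analysis
#'
#' Tests (i) the single-feature minus two-feature template-similarity
#' difference within each region, using nulls built by shuffling trial
#' condition labels within run; (ii) the between-region difference in mean
#' template similarity and (iii) the region x condition interaction, using
#' nulls built by randomly swapping the two regions' values trial by trial
#' (the trials are shared, so region assignment is exchangeable under the
#' null). All p-values are one-sided in the direction of the observed
#' effect's hypothesized sign (`sign_*` arguments, default +1).
#'
#' @param result_a,result_b `content_result` objects for two regions over
#'   the same trials.
#' @param n_perm Number of permutations (minimum 100, default 1000).
#' @param seed Integer seed.
#' @param sign_condition,sign_region,sign_interaction Test directions.
#' @return List of lists with `observed` and `p` for: `condition_a`,
#'   `condition_b` (single - two within region), `region` (mean a - b),
#'   `interaction` ((single - two)_a - (single - two)_b).
#' @export
content_contrast <- function(result_a, result_b, n_perm = 1000, seed = 1,
                             sign_condition = 1, sign_region = 1,
                             sign_interaction = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  ta <- result_a$per_trial; tb <- result_b$per_trial
  if (nrow(ta) != nrow(tb) ||
      !all(ta$run == tb$run & ta$trial == tb$trial)) {
    stop("regions have mismatched run/trial structure", call. = FALSE)
  }
  cond_diff <- function(z, cond) {
    mean(z[cond == "single_feature"]) - mean(z[cond == "two_feature"])
  }
  obs <- list(
    condition_a = cond_diff(ta$z, ta$condition),
    condition_b = cond_diff(tb$z, tb$condition),
    region = mean(ta$z) - mean(tb$z),
    interaction = cond_diff(ta$z, ta$condition) -
      cond_diff(tb$z, tb$condition)
  )
  set.seed(as.integer(seed))
  n <- nrow(ta)
  runs <- unique(ta$run)
  null_ca <- numeric(n_perm); null_cb <- numeric(n_perm)
  null_rg <- numeric(n_perm); null_ix <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    # within-run shuffles of condition labels
    cond_perm <- ta$condition
    for (r in runs) {
      idx <- which(ta$run == r)
      cond_perm[idx] <- cond_perm[sample(idx)]
    }
    null_ca[b] <- cond_diff(ta$z, cond_perm)
    null_cb[b] <- cond_diff(tb$z, cond_perm)
    # trial-wise region swaps
    swap <- stats::runif(n) < 0.5
    za <- ifelse(swap, tb$z, ta$z)
    zb <- ifelse(swap, ta$z, tb$z)
    null_rg[b] <- mean(za) - mean(zb)
    null_ix[b] <- cond_diff(za, ta$condition) - cond_diff(zb, tb$condition)
  }
  pval <- function(o, nulls, s) (1 + sum(s * nulls >= s * o)) / (1 + n_perm)
  list(
    condition_a = list(observed = obs$condition_a,
                       p = pval(obs$condition_a, null_ca, sign_condition)),
    condition_b = list(observed = obs$condition_b,
                       p = pval(obs$condition_b, null_cb, sign_condition)),
    region = list(observed = obs$region,
                  p = pval(obs$region, null_rg, sign_region)),
    interaction = list(observed = obs$interaction,
                       p = pval(obs$interaction, null_ix, sign_interaction))
  )
}
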