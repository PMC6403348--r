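#' Configuration for the full synthetic-data analysis pipeline
#'
#' Collects every knob the end-to-end analysis needs. All randomness derives
#' from `seed`: each stage uses a fixed offset substream, so identical
#' configurations reproduce identical outputs.
#'
#' @param n_subjects Number of simulated subjects (default 30).
#' @param n_runs,trials_per_stimulus,p_high,p_low Trial-sequence settings.
#' @param behavior A [behavior_config()] providing the generating behavioral
#'   model (its seed field is overridden per subject).
#' @param models Model kinds entered into the comparison.
#' @param n_restarts Restarts per model fit (default 10).
#' @param bms_n_mc Monte-Carlo samples for exceedance probabilities.
#' @param psa_n_perm Permutations for pattern-similarity tests.
#' @param pattern_hippocampus,pattern_cortex [pattern_config()]s for the two
#'   simulated regions (defaults: a pattern-separated "conjunctive" region
#'   and an "additive" feature-mixing region).
#' @param striatal_weights,striatal_noise_sd Generative weights and noise of
#'   the striatal activation estimates.
#' @param blocks_per_category Localizer blocks per category.
#' @param out_dir Output directory (NULL: nothing written).
#' @param seed Master integer seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_subjects = 30, n_runs = 3,
                            trials_per_stimulus = 10,
                            p_high = 0.7, p_low = 0.3,
                            behavior = behavior_config(),
                            models = c("no_learning", "feature",
                                       "conjunctive", "value_spread"),
                            n_restarts = 10,
                            bms_n_mc = 1e6,
                            psa_n_perm = 1000,
                            pattern_hippocampus =
                              pattern_config(mode = "conjunctive",
                                             region = "hippocampus"),
                            pattern_cortex =
                              pattern_config(mode = "additive",
                                             region = "cortex"),
                            striatal_weights = c(w_target = 2,
                                                 w_feature = 1,
                                                 w_conj = 0.5),
                            striatal_noise_sd = 1,
                            blocks_per_category = 6,
                            out_dir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> fit -> compare -> prediction-error regressors ->
#' striatal decomposition -> pattern-similarity analysis -> pattern content
#' -> run-level brain-behavior coupling on generated data, and (optionally)
#' writes per-stage TSV/JSON outputs plus a consolidated report to
#' `cfg$out_dir`. Identical configurations (including the seed) produce
#' identical results.
#'
#' @param cfg An [analysis_config()].
#' @return List with elements `sequence`, `behavior` (per-subject list),
#'   `cv` (subjects x models CV log-likelihood matrix and per-trial
#'   version), `bms`, `fits`, `index`, `pe_regressors`, `striatal`, `psa`,
#'   `content`, `coupling`, `config`.
#' @export
run_full_analysis <- function(cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"))
  seed <- as.integer(cfg$seed)
  seq <- make_trial_sequence(cfg$n_runs, cfg$trials_per_stimulus,
                             cfg$p_high, cfg$p_low, seed = seed)
  models <- cfg$models
  n_sub <- cfg$n_subjects
  subjects <- sprintf("sub%02d", seq_len(n_sub))

  ## --- behavior: simulate, fit, cross-validate -------------------------
  behavior <- vector("list", n_sub); names(behavior) <- subjects
  cv_total <- matrix(NA_real_, n_sub, length(models),
                     dimnames = list(subjects, models))
  cv_per_trial <- cv_total
  fits <- vector("list", n_sub); names(fits) <- subjects
  for (s in seq_len(n_sub)) {
    bcfg <- cfg$behavior
    bcfg$seed <- seed + 1000L + s
    behavior[[s]] <- simulate_behavior(seq, bcfg)
    fits[[s]] <- lapply(stats::setNames(models, models), function(m) {
      fit_model(behavior[[s]], m, n_restarts = cfg$n_restarts,
                seed = seed + 2000L + s)
    })
    for (m in models) {
      cv <- cv_predictive_likelihood(behavior[[s]], m,
                                     n_restarts = cfg$n_restarts,
                                     seed = seed + 3000L + s)
      cv_total[s, m] <- cv$total_ll
      cv_per_trial[s, m] <- cv$per_trial_ll
    }
  }

  bms <- group_bms(cv_total, n_mc = cfg$bms_n_mc, seed = seed + 11L)

  ## --- per-run conjunctive-learning index ------------------------------
  index <- NULL
  if (all(c("value_spread", "conjunctive", "no_learning") %in% models)) {
    index <- do.call(rbind, lapply(subjects, function(sb) {
      ix <- conjunctive_learning_index(behavior[[sb]],
                                       fits[[sb]]$value_spread,
                                       fits[[sb]]$conjunctive,
                                       fits[[sb]]$no_learning)
      cbind(subject = sb, ix)
    }))
  }

  ## --- prediction-error regressors and striatal decomposition ----------
  med_alpha_f <- stats::median(vapply(fits, function(f)
    f$feature$params$alpha, numeric(1)))
  med_alpha_c <- stats::median(vapply(fits, function(f)
    f$conjunctive$params$alpha, numeric(1)))
  regs <- build_pe_regressors(seq,
                              model_params("feature", alpha = med_alpha_f),
                              model_params("conjunctive",
                                           alpha = med_alpha_c))
  betas <- unlist(lapply(seq_len(n_sub), function(s) {
    simulate_striatal_betas(regs, cfg$striatal_weights,
                            cfg$striatal_noise_sd, seed = seed + 4000L + s)
  }))
  subject_ids <- rep(subjects, each = nrow(regs))
  striatal <- striatal_beta_regression(betas, regs, subject_ids)

  ## --- pattern-similarity analysis -------------------------------------
  gen_trace <- run_model(seq, cfg$behavior$params)
  design <- build_psa_design(seq, gen_trace, epoch_interaction = TRUE)
  region_cfgs <- list(hippocampus = cfg$pattern_hippocampus,
                      cortex = cfg$pattern_cortex)
  psa <- list()
  run_overlap <- list()
  for (rg in names(region_cfgs)) {
    pcfg <- region_cfgs[[rg]]
    zbar <- NULL
    per_run_coef <- NULL
    for (s in seq_len(n_sub)) {
      pcfg_s <- pcfg
      pcfg_s$seed <- seed + 5000L + s + 500L * match(rg, names(region_cfgs))
      pat <- simulate_patterns(seq, gen_trace, pcfg_s,
                               basis = make_pattern_basis(pcfg$n_units,
                                                          seed = seed))
      psm <- compute_psm(pat)
      zbar <- if (is.null(zbar)) psm$z else zbar + psm$z
      for (r in sort(unique(seq$run))) {
        sel <- pat$meta$run == r
        pat_r <- pattern_dataset(pat$x[sel, , drop = FALSE],
                                 pat$meta[sel, , drop = FALSE], rg)
        seq_r <- seq[seq$run == r, , drop = FALSE]
        tr_r <- gen_trace[gen_trace$run == r, , drop = FALSE]
        co <- fit_psm_regression(compute_psm(pat_r),
                                 build_psa_design(seq_r, tr_r))
        per_run_coef <- rbind(per_run_coef,
                              data.frame(subject = subjects[s], run = r,
                                         overlap = co[["overlap"]],
                                         within = co[["within_stimulus"]]))
      }
    }
    group_psm <- compute_psm_from_z(zbar / n_sub, attr(design, "pairs"),
                                    rg, attr(design, "n_trials"))
    coef <- fit_psm_regression(group_psm, design)
    perm <- permutation_test(group_psm, design,
                             c("within_stimulus", "overlap",
                               "value_similarity", "value_x_epoch"),
                             n_perm = cfg$psa_n_perm, seed = seed + 21L)
    psa[[rg]] <- list(coefficients = coef, permutation = lapply(perm,
                        function(x) x[c("observed", "p")]))
    run_overlap[[rg]] <- per_run_coef
  }

  ## --- run-level coupling ----------------------------------------------
  conj_run <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    b <- betas[subject_ids == subjects[s]]
    do.call(rbind, lapply(sort(unique(seq$run)), function(r) {
      sel <- regs$run == r
      X <- cbind(1, regs$target[sel], regs$z_feature_pe[sel],
                 regs$z_conj_diff[sel])
      cf <- qr.coef(qr(X), b[sel])
      data.frame(subject = subjects[s], run = r, conj_beta = cf[4])
    }))
  }))
  hip <- run_overlap$hippocampus
  merged <- merge(hip, conj_run, by = c("subject", "run"))
  coupling <- brain_behavior_coupling(merged$overlap, merged$conj_beta,
                                      merged$subject)

  ## --- pattern content --------------------------------------------------
  basis <- make_pattern_basis(cfg$pattern_hippocampus$n_units, seed = seed)
  mapping <- make_feature_category_mapping(cfg$n_runs,
                                           rownames(basis$category))
  content_results <- list()
  for (rg in names(region_cfgs)) {
    pcfg <- region_cfgs[[rg]]
    per_trial_z <- NULL
    template_ref <- NULL
    for (s in seq_len(n_sub)) {
      pcfg_s <- pcfg
      pcfg_s$seed <- seed + 7000L + s + 500L * match(rg, names(region_cfgs))
      pat <- simulate_patterns(seq, gen_trace, pcfg_s, basis = basis,
                               mapping = mapping)
      loc <- simulate_localizer(rownames(basis$category),
                                cfg$blocks_per_category, pcfg_s, basis,
                                seed = seed + 8000L + s)
      res <- template_similarity(pat, build_templates(loc), mapping)
      per_trial_z <- if (is.null(per_trial_z)) res$per_trial$z else
        per_trial_z + res$per_trial$z
      template_ref <- res
    }
    template_ref$per_trial$z <- per_trial_z / n_sub
    agg <- stats::aggregate(z ~ run + condition, template_ref$per_trial,
                            mean)
    template_ref$per_run <- agg
    template_ref$condition_means <- tapply(agg$z, agg$condition, mean)
    content_results[[rg]] <- template_ref
  }
  content <- list(
    results = content_results,
    contrast = content_contrast(content_results$hippocampus,
                                content_results$cortex,
                                n_perm = max(cfg$psa_n_perm, 100),
                                seed = seed + 31L,
                                sign_region = -1, sign_interaction = 1)
  )

  out <- list(sequence = seq, behavior = behavior,
              cv = list(total = cv_total, per_trial = cv_per_trial),
              bms = bms, fits = fits, index = index,
              pe_regressors = regs, striatal = striatal, psa = psa,
              run_overlap = run_overlap, coupling = coupling,
              content = content, config = cfg)
  if (!is.null(cfg$out_dir)) write_report(out, cfg$out_dir)
  out
}

# Rebuild a psm object from externally averaged Fisher-z values.
compute_psm_from_z <- function(z, pairs, region, n_trials) {
  structure(data.frame(i = pairs$i, j = pairs$j, z = z, ok = is.finite(z)),
            region = region, n_trials = n_trials,
            class = c("psm", "data.frame"))
}

#' Write the consolidated pipeline report
#'
#' Emits the trial sequence and per-subject behavior as TSV, fit and
#' model-comparison summaries, pattern-similarity coefficients and
#' permutation p-values, content and coupling results as JSON, plus a
#' consolidated `report.json` carrying the seed and settings.
#'
#' @param results A [run_full_analysis()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_sequence(results$sequence, file.path(out_dir, "sequence.tsv"))
  beh <- do.call(rbind, lapply(names(results$behavior), function(sb) {
    cbind(subject = sb, as.data.frame(results$behavior[[sb]]))
  }))
  write_behavior_tsv(beh, file.path(out_dir, "behavior.tsv"))
  utils::write.table(cbind(subject = rownames(results$cv$total),
                           as.data.frame(results$cv$total)),
                     file.path(out_dir, "cv_log_likelihood.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bms_json(results$bms, file.path(out_dir, "bms.json"))
  if (!is.null(results$index)) {
    utils::write.table(results$index, file.path(out_dir, "index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(
    seed = results$config$seed,
    n_subjects = results$config$n_subjects,
    models = results$config$models,
    bms = list(pep = as.list(results$bms$pep), bor = results$bms$bor),
    striatal = list(coefficients = as.list(results$striatal$coefficients),
                    t = as.list(results$striatal$t)),
    psa = lapply(results$psa, function(x) {
      list(coefficients = as.list(x$coefficients),
           p = lapply(x$permutation, `[[`, "p"))
    }),
    content = lapply(results$content$contrast, function(x)
      x[c("observed", "p")]),
    coupling = results$coupling[c("slope", "t", "p", "df")]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
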