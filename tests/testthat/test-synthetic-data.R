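test_that("noiseless behavior orders reaction times by stimulus value", {
  seq <- make_trial_sequence(seed = 1)
  cfg <- behavior_config(rt_noise_sd = 0, seed = 2)
  b <- simulate_behavior(seq, cfg)
  rt_mean <- tapply(b$rt[b$target == 1], b$stimulus[b$target == 1], mean)
  # value-spread values: AB and C high, AC middle, B low -> RT ordering
  expect_lt(rt_mean[["AB"]], rt_mean[["AC"]])
  expect_lt(rt_mean[["AC"]], rt_mean[["B"]])
  expect_lt(rt_mean[["C"]], rt_mean[["B"]])
  # log RT reproduces the linear model exactly at zero noise
  tr <- run_model(seq, cfg$params)
  resp <- b$responded == 1
  expect_equal(b$log_rt[resp],
               cfg$rt_intercept + cfg$value_slope * tr$v[resp],
               tolerance = 1e-12)
})

test_that("a non-learning subject hits on about half of target trials", {
  seq <- make_trial_sequence(1, 250, mode = "bernoulli", seed = 3,
                             strict = FALSE)
  cfg <- behavior_config(params = model_params("no_learning"),
                         value_slope = 0, seed = 4)
  b <- simulate_behavior(seq, cfg)
  hit_rate <- mean(b$hit[b$target == 1])
  n_targ <- sum(b$target == 1)
  expect_lt(abs(hit_rate - 0.5), 4 * sqrt(0.25 / n_targ) + 0.02)
})

test_that("rewards follow the payoff rule and labels are consistent", {
  b <- make_subject(seed = 12)
  expect_true(all(b$reward[b$outcome == "hit"] == 0.25))
  expect_true(all(b$reward[b$outcome == "false_alarm"] == -0.25))
  expect_true(all(b$reward[b$outcome %in% c("miss",
                                            "correct_rejection")] == 0))
  expect_true(all(is.na(b$rt[b$responded == 0])))
  expect_true(all(is.finite(b$log_rt[b$responded == 1])))
  expect_true(all(b$false_alarm[b$target == 1] == 0))
  expect_true(all(b$hit[b$target == 0] == 0))
  # threshold moves in 10 ms task-step increments, only after target trials
  steps <- round(diff(b$threshold), 10)
  expect_true(all(steps %in% c(-0.010, 0, 0.010)))
  expect_true(all(steps[b$target[-nrow(b)] == 0] == 0))
})

test_that("behavioral simulation is reproducible from its seed", {
  seq <- make_trial_sequence(seed = 1)
  b1 <- simulate_behavior(seq, behavior_config(seed = 5))
  b2 <- simulate_behavior(seq, behavior_config(seed = 5))
  expect_identical(as.data.frame(b1), as.data.frame(b2))
})

test_that("model fitting on simulated behavior recovers the learning rate on average", {
  alphas <- vapply(1:12, function(s) {
    d <- make_subject(seed = 500 + s,
                      params = model_params("conjunctive", alpha = 0.3))
    fit_model(d, "conjunctive", n_restarts = 8, seed = s)$params$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 0.3), 0.15)
})

test_that("pattern generation with no shared components yields stimulus-specific similarity only", {
  seq <- make_trial_sequence(seed = 1)
  tr <- run_model(seq, model_params("value_spread", alpha = .3,
                                    omega = .44))
  des <- build_psa_design(seq, tr)
  # conjunctive mode with no feature components: within > 0, overlap ~ 0
  co <- fit_psm_regression(
    compute_psm(simulate_patterns(seq, tr,
                                  pattern_config(mode = "conjunctive",
                                                 overlap_strength = 0,
                                                 value_slope = 0,
                                                 seed = 21))), des)
  expect_gt(co[["within_stimulus"]], 0.03)
  expect_lt(abs(co[["overlap"]]), 0.015)
  # additive mode: overlap clearly positive
  co2 <- fit_psm_regression(
    compute_psm(simulate_patterns(seq, tr,
                                  pattern_config(mode = "additive",
                                                 value_slope = 0,
                                                 seed = 22))), des)
  expect_gt(co2[["overlap"]], 0.01)
})

test_that("pure-noise patterns produce null similarity structure", {
  seq <- make_trial_sequence(seed = 1)
  tr <- run_model(seq, model_params("value_spread", alpha = .3,
                                    omega = .44))
  des <- build_psa_design(seq, tr)
  psm <- compute_psm(simulate_patterns(seq, tr,
                                       pattern_config(within_strength = 0,
                                                      overlap_strength = 0,
                                                      value_slope = 0,
                                                      seed = 23)))
  out <- permutation_test(psm, des, c("within_stimulus", "overlap"),
                          n_perm = 300, seed = 3)
  expect_gt(out$within_stimulus$p, 0.01)
  expect_gt(out$overlap$p, 0.01)
})

test_that("noiseless striatal betas and localizer blocks reproduce their generators", {
  seq <- make_trial_sequence(seed = 1)
  regs <- build_pe_regressors(seq, model_params("feature", alpha = .3),
                              model_params("conjunctive", alpha = .3))
  b <- simulate_striatal_betas(regs, c(w_target = 2, w_feature = 1,
                                       w_conj = 0.5), noise_sd = 0,
                               seed = 1)
  expect_equal(b, 2 * regs$target + regs$z_feature_pe +
                 0.5 * regs$z_conj_diff, tolerance = 1e-12)

  basis <- make_pattern_basis(40, seed = 2)
  loc <- simulate_localizer(cfg = pattern_config(n_units = 40,
                                                 noise_sd = 0, seed = 2),
                            basis = basis, seed = 3)
  tpl <- build_templates(loc)
  expect_equal(tpl$templates[rownames(basis$category), ],
               basis$category, tolerance = 1e-12)
})

test_that("label permutation destroys template specificity", {
  seq <- make_trial_sequence(seed = 1)
  tr <- run_model(seq, model_params("conjunctive", alpha = .3))
  basis <- make_pattern_basis(60, seed = 4)
  mapping <- make_feature_category_mapping(3)
  pat <- simulate_patterns(seq, tr, pattern_config(mode = "additive",
                                                   value_slope = 0,
                                                   seed = 5), basis,
                           mapping)
  tpl <- build_templates(simulate_localizer(cfg = pattern_config(seed = 4),
                                            basis = basis, seed = 6))
  res <- template_similarity(pat, tpl, mapping)
  set.seed(7)
  shuffled <- pat
  shuffled$x <- pat$x[sample(nrow(pat$x)), ]
  res_shuf <- template_similarity(shuffled, tpl, mapping)
  expect_gt(mean(res$per_trial$z), 0.1)
  # a shuffled trial only matches its slot's template by chance, so the
  # mean similarity collapses toward the chance-overlap baseline
  expect_lt(mean(res_shuf$per_trial$z), 0.6 * mean(res$per_trial$z))
})
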