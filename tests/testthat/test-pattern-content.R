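test_that("templates are category means and degenerate templates are flagged", {
  set.seed(17)
  x <- rbind(matrix(rnorm(3 * 20), 3, 20),      # faces
             matrix(rnorm(2 * 20), 2, 20))      # houses
  meta <- data.frame(run = 0L, trial = 0:4,
                     category = c("face", "face", "face", "house", "house"))
  tpl <- build_templates(pattern_dataset(x, meta, "loc"))
  # loop-based mean oracle
  for (k in 1:20) {
    expect_equal(unname(tpl$templates["face", k]),
                 (x[1, k] + x[2, k] + x[3, k]) / 3, tolerance = 1e-12)
  }
  expect_equal(unname(tpl$templates["house", ]),
               unname(colMeans(x[4:5, ])), tolerance = 1e-12)
  expect_false(any(tpl$degenerate))

  # identical blocks: the template is that pattern exactly
  x2 <- rbind(x[1, ], x[1, ], -x[1, ], x[1, ] * 0 + 1)
  meta2 <- data.frame(run = 0L, trial = 0:3,
                      category = c("a", "a", "b", "b"))
  # category b blocks: (-v, constant) -> mean is (1 - v)/2, fine; build a
  # true cancellation instead
  x3 <- rbind(x[1, ], x[1, ], x[2, ], -x[2, ])
  meta3 <- data.frame(run = 0L, trial = 0:3,
                      category = c("a", "a", "b", "b"))
  tpl3 <- build_templates(pattern_dataset(x3, meta3, "loc"))
  expect_equal(tpl3$templates["a", ], x[1, ], tolerance = 1e-12)
  expect_true(tpl3$degenerate[["b"]])
  expect_error(build_templates(pattern_dataset(x3, meta3[, 1:2], "loc")),
               "category")
})

test_that("task-template similarity is extreme for perfect matches and null for orthogonal patterns", {
  basis <- make_pattern_basis(40, seed = 2)
  mapping <- make_feature_category_mapping(1)
  tpl <- structure(list(templates = basis$category,
                        n_blocks = stats::setNames(rep(1L, 3),
                                                   rownames(basis$category)),
                        degenerate = stats::setNames(rep(FALSE, 3),
                                                     rownames(basis$category))),
                   class = "template_set")
  cat_b <- mapping$category[mapping$feature == "B"]
  cat_c <- mapping$category[mapping$feature == "C"]
  x <- rbind(tpl$templates[cat_b, ],                  # B = its template
             basis$stimulus["AB", ])                  # AB orthogonal
  meta <- data.frame(run = 0L, trial = 0:1, stimulus = c("B", "AB"),
                     target = c(0L, 1L))
  res <- template_similarity(pattern_dataset(x, meta, "roi"), tpl, mapping)
  expect_equal(res$per_trial$z[1], atanh(1 - 1e-7), tolerance = 1e-6)
  expect_lt(abs(res$per_trial$z[2]), 0.35)  # orthogonal up to mean-centering
  expect_equal(res$per_trial$condition, c("single_feature", "two_feature"))
  # AB and B are scored against the same template within the run
  expect_equal(res$per_trial$category, rep(cat_b, 2))
})

test_that("conjunctive and additive generative modes reproduce the predicted content ordering", {
  seq <- make_trial_sequence(seed = 1)
  tr <- run_model(seq, model_params("value_spread", alpha = .3,
                                    omega = .44))
  basis <- make_pattern_basis(60, seed = 1)
  mapping <- make_feature_category_mapping(3)
  loc <- simulate_localizer(cfg = pattern_config(seed = 1), basis = basis,
                            seed = 3)
  tpl <- build_templates(loc)
  mean_h <- c(single_feature = 0, two_feature = 0)
  mean_c <- mean_h
  n_rep <- 4
  for (s in 1:n_rep) {
    ph <- simulate_patterns(seq, tr,
                            pattern_config(mode = "conjunctive",
                                           seed = 40 + s), basis, mapping)
    pc <- simulate_patterns(seq, tr,
                            pattern_config(mode = "additive",
                                           seed = 60 + s), basis, mapping)
    mean_h <- mean_h + template_similarity(ph, tpl, mapping)$condition_means / n_rep
    mean_c <- mean_c + template_similarity(pc, tpl, mapping)$condition_means / n_rep
  }
  # pattern-separated region: single-feature similarity high, two-feature ~0
  expect_gt(mean_h[["single_feature"]], mean_h[["two_feature"]] + 0.1)
  expect_lt(abs(mean_h[["two_feature"]]), 0.05)
  # additive region: two-feature at least as similar as single-feature
  expect_gt(mean_c[["two_feature"]], mean_c[["single_feature"]] - 0.02)
  expect_gt(mean_c[["two_feature"]], 0.2)
})

test_that("content contrasts separate conjunctive from additive regions and are null when identical", {
  seq <- make_trial_sequence(seed = 1)
  tr <- run_model(seq, model_params("value_spread", alpha = .3,
                                    omega = .44))
  basis <- make_pattern_basis(60, seed = 1)
  mapping <- make_feature_category_mapping(3)
  tpl <- build_templates(simulate_localizer(cfg = pattern_config(seed = 1),
                                            basis = basis, seed = 5))
  res_h <- template_similarity(
    simulate_patterns(seq, tr, pattern_config(mode = "conjunctive",
                                              seed = 7), basis, mapping),
    tpl, mapping)
  res_c <- template_similarity(
    simulate_patterns(seq, tr, pattern_config(mode = "additive",
                                              seed = 8), basis, mapping),
    tpl, mapping)
  ct <- content_contrast(res_h, res_c, n_perm = 500, seed = 9,
                         sign_region = -1, sign_interaction = 1)
  expect_lt(ct$condition_a$p, 0.05)       # single > two in conjunctive region
  expect_lt(ct$interaction$p, 0.05)       # effect larger than in additive
  expect_lt(ct$region$p, 0.05)            # lower overall template similarity

  same <- content_contrast(res_h, res_h, n_perm = 300, seed = 10)
  expect_equal(same$interaction$observed, 0, tolerance = 1e-12)
  expect_gt(same$interaction$p, 0.1)
  expect_error(content_contrast(res_h, res_c, n_perm = 50), "at least 100")
})

test_that("relabeling categories with an updated mapping leaves condition means invariant", {
  seq <- make_trial_sequence(seed = 2)
  tr <- run_model(seq, model_params("conjunctive", alpha = .3))
  basis <- make_pattern_basis(60, seed = 3)
  mapping <- make_feature_category_mapping(3, counterbalance = FALSE)
  pat <- simulate_patterns(seq, tr, pattern_config(mode = "additive",
                                                   seed = 4), basis,
                           mapping)
  tpl <- build_templates(simulate_localizer(cfg = pattern_config(seed = 3),
                                            basis = basis, seed = 6))
  res1 <- template_similarity(pat, tpl, mapping)
  # swap which categories play features B and C, regenerating patterns
  # under the swapped mapping: the condition means must be unchanged in
  # distributional structure (identical here because the basis vectors are
  # exchangeable and the noise seed is fixed)
  swapped <- mapping
  swapped$category[swapped$feature == "B"] <-
    mapping$category[mapping$feature == "C"]
  swapped$category[swapped$feature == "C"] <-
    mapping$category[mapping$feature == "B"]
  pat2 <- simulate_patterns(seq, tr, pattern_config(mode = "additive",
                                                    seed = 4), basis,
                            swapped)
  res2 <- template_similarity(pat2, tpl, swapped)
  expect_lt(max(abs(res1$condition_means - res2$condition_means)), 0.06)
})
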