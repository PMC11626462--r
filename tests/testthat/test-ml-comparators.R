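test_that("inverse-probability weights balance the classes and sum to N", {
  w <- imbalance_weights(rep(c(1, 0), c(10, 90)))
  expect_equal(unique(w[1:10]), 5)
  expect_equal(unique(w[11:100]), 5 / 9)
  expect_equal(sum(w), 100)
  expect_equal(sum(w[1:10]), sum(w[11:100]))
  expect_equal(imbalance_weights(c(1, 1, 0, 0)), rep(1, 4))
  withr::with_seed(3, {
    for (i in 1:20) {
      y <- c(0, 1, rbinom(sample(5:50, 1), 1, runif(1, 0.1, 0.9)))
      expect_equal(sum(imbalance_weights(y)), length(y))
    }
  })
  expect_error(imbalance_weights(c(1, 1)), class = "jembuild_single_class")
})

test_that("tuning selects the grid point with the best cross-validated AUC", {
  # a single-variable deterministic signal: any family should reach CV AUC ~1
  d <- group_keyed_cohort(n_pcs = 4, naf_per_pcs = 2, group_size = 60,
                          p_hi = 1, p_lo = 0, seed = 2)
  design <- dummy_encode(d, pcs_depth = NA, naf_depth = 5)
  y <- d$exposure
  fit <- tune_learner("tree", design, y,
                      grid = tibble::tibble(maxdepth = 8L, minbucket = 5L),
                      folds = 5, seed = 1)
  expect_equal(nrow(fit$cv_results), 1L)  # grid of one -> that point
  expect_gt(fit$cv_auc, 0.99)
  # never selects a grid point with strictly lower mean CV AUC
  fit2 <- tune_learner("tree", design, y, grid = default_grid("tree"),
                       folds = 5, seed = 1)
  expect_equal(fit2$cv_auc, max(fit2$cv_results$cv_auc))
})

test_that("a depth-limited tree loses to a deeper one on an interaction signal", {
  # XOR of two indicator blocks: depth-1 stumps cannot express it
  withr::with_seed(4, {
    a <- rbinom(600, 1, 0.5)
    b <- rbinom(600, 1, 0.5)
  })
  y <- as.integer(xor(a, b))
  design <- cbind(pcs1_4 = a, naf1_8 = b)
  fit <- tune_learner("tree", design, y,
                      grid = tibble::tibble(maxdepth = c(1L, 4L),
                                            minbucket = c(5L, 5L)),
                      folds = 5, seed = 2)
  expect_equal(fit$params$maxdepth, 4L)
})

test_that("weighted CV AUC is invariant to rescaling the weights", {
  d <- group_keyed_cohort(n_pcs = 4, naf_per_pcs = 2, group_size = 40,
                          p_hi = 0.8, p_lo = 0.2, seed = 5)
  design <- dummy_encode(d, pcs_depth = NA, naf_depth = 5)
  w <- imbalance_weights(d$exposure)
  f1 <- tune_learner("tree", design, d$exposure, weights = w,
                     grid = tibble::tibble(maxdepth = 4L, minbucket = 5L),
                     folds = 5, seed = 3)
  f2 <- tune_learner("tree", design, d$exposure, weights = 7 * w,
                     grid = tibble::tibble(maxdepth = 4L, minbucket = 5L),
                     folds = 5, seed = 3)
  expect_equal(f1$cv_auc, f2$cv_auc, tolerance = 1e-10)
})

test_that("a saturated unweighted tree reproduces the group frequencies", {
  # 3 groups with distinct exposed fractions; full-depth variable set
  d <- tibble::tibble(
    pcs = rep(c("431f", "432a", "526b"), c(30, 30, 30)),
    naf = rep(c("8610z", "8610z", "8710a"), c(30, 30, 30)),
    exposure = c(rep(c(1, 0), c(6, 24)),   # 0.2
                 rep(c(1, 0), c(15, 15)),  # 0.5
                 rep(c(1, 0), c(27, 3)))   # 0.9
  )
  d <- add_group_key(d, "standard")
  design <- dummy_encode(d, pcs_depth = 4, naf_depth = 5)
  fit <- tune_learner("tree", design, d$exposure,
                      weights = rep(1, nrow(d)),
                      grid = tibble::tibble(maxdepth = 30L, minbucket = 1L),
                      folds = 3, seed = 1)
  fit$variable_set <- list(pcs_depth = 4L, naf_depth = 5L)
  groups <- dplyr::distinct(d, group_key, pcs, naf)
  probs <- predict_group_probabilities(fit, groups)
  freqs <- estimate_frequencies(d, "exposure")
  j <- dplyr::left_join(probs, freqs, by = "group_key")
  expect_equal(j$probability, j$frequency, tolerance = 1e-12)
})

test_that("variable-set selection finds the generative depth", {
  # exposure keyed to the full occupation x sector pair
  d <- group_keyed_cohort(n_pcs = 6, naf_per_pcs = 4, group_size = 50,
                          p_hi = 0.9, p_lo = 0.1, seed = 7)
  sets <- tibble::tibble(pcs_depth = c(4L, NA, 4L),
                         naf_depth = c(NA, 5L, 5L))
  fit <- select_variable_set(d, "exposure", family = "tree", sets = sets,
                             grid = tibble::tibble(maxdepth = 30L,
                                                   minbucket = 5L),
                             folds = 5, seed = 1)
  # occupation alone carries no signal here; the winning set must use naf
  expect_false(is.na(fit$variable_set$naf_depth))
  expect_equal(nrow(fit$set_results), 3L)
  best <- which.max(fit$set_results$cv_auc)
  expect_equal(fit$cv_auc, fit$set_results$cv_auc[best])
})

test_that("sets whose design is empty are skipped, all-skipped errors", {
  d <- tibble::tibble(pcs = rep("431f", 40), naf = rep("86", 40),
                      exposure = rep(c(0, 1), 20))
  expect_error(
    select_variable_set(d, "exposure", family = "tree",
                        sets = tibble::tibble(pcs_depth = 4L,
                                              naf_depth = NA_integer_),
                        grid = tibble::tibble(maxdepth = 2L, minbucket = 5L),
                        folds = 2, seed = 1),
    class = "jembuild_empty_design"
  )
})

test_that("group probability predictions are constant within groups and bounded", {
  d <- group_keyed_cohort(n_pcs = 4, naf_per_pcs = 2, group_size = 50,
                          p_hi = 0.7, p_lo = 0.3, seed = 8)
  design <- dummy_encode(d, pcs_depth = 4, naf_depth = NA)
  fit <- tune_learner("forest", design, d$exposure,
                      grid = tibble::tibble(num_trees = 50L,
                                            mtry_rule = "sqrt"),
                      folds = 3, seed = 2)
  fit$variable_set <- list(pcs_depth = 4L, naf_depth = NA_integer_)
  groups <- dplyr::distinct(d, pcs, naf)
  probs <- predict_group_probabilities(fit, groups)
  expect_true(all(probs$probability >= 0 & probs$probability <= 1))
  # groups identical at the model's depths (same occupation, different
  # sector) get identical probabilities
  same <- dplyr::group_by(probs, pcs)
  expect_true(all(dplyr::summarise(same, v = dplyr::n_distinct(probability))$v == 1))
  # unseen code values are unrepresentable
  expect_error(
    predict_group_probabilities(fit, tibble::tibble(pcs = "9z99", naf = "86")),
    class = "jembuild_unrepresentable_group"
  )
})

test_that("all methods agree on strongly group-determined data", {
  sep <- make_separable_cohort(n = 1600, n_groups = 8, gap = 0.8, seed = 10)
  cmp <- compare_methods(
    sep$records, "exposure", specs = binary_spec(),
    seed = 4, sets = tibble::tibble(pcs_depth = 4L, naf_depth = 5L),
    grids = tiny_grids(), folds = 5, n_boot = 100
  )
  expect_equal(nrow(cmp), 4L)
  expect_true("frequency" %in% cmp$method)
  expect_true(all(cmp$auc >= cmp$auc_lo & cmp$auc <= cmp$auc_hi))
  # overlapping intervals: similar discriminatory power
  expect_lt(max(cmp$auc_lo), min(cmp$auc_hi))
})

test_that("bootstrap intervals narrow as the test sample grows", {
  w_small <- compare_methods(
    make_separable_cohort(600, 6, 0.6, seed = 2)$records, "exposure",
    methods = "frequency", specs = binary_spec(), seed = 3, n_boot = 200
  )
  w_big <- compare_methods(
    make_separable_cohort(4800, 6, 0.6, seed = 2)$records, "exposure",
    methods = "frequency", specs = binary_spec(), seed = 3, n_boot = 200
  )
  expect_lt(w_big$auc_hi - w_big$auc_lo, w_small$auc_hi - w_small$auc_lo)
})
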