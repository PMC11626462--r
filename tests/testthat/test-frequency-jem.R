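test_that("the 70/30 split is exact, exhaustive and seed-reproducible", {
  d <- tibble::tibble(x = 1:10)
  s <- split_cohort(d, 0.7, seed = 3)
  expect_equal(sum(s$split == "learning"), 7L)
  expect_equal(sum(s$split == "test"), 3L)
  expect_identical(split_cohort(d, 0.7, seed = 3), s)
  expect_false(identical(split_cohort(d, 0.7, seed = 4)$split, s$split))
  big <- tibble::tibble(x = seq_len(12489))
  expect_equal(sum(split_cohort(big, 0.7, seed = 1)$split == "learning"), 8742L)
})

test_that("groups of 10 or fewer complete-case members are excluded", {
  d <- tibble::tibble(
    group_key = rep(c("a", "b", "c"), c(5, 11, 200)),
    e = 0
  )
  ex <- exclude_small_groups(d)
  expect_setequal(unique(ex$records$group_key), c("b", "c"))
  expect_equal(nrow(ex$records), 211L)
  expect_equal(ex$groups$retained[match(c("a", "b", "c"), ex$groups$group_key)],
               c(FALSE, TRUE, TRUE))
  expect_error(exclude_small_groups(tibble::tibble(group_key = rep("a", 3))),
               class = "jembuild_no_groups")
})

test_that("group frequencies are exposed fractions of complete-case members", {
  d <- tibble::tibble(group_key = rep(c("g1", "g2"), c(20, 15)),
                      e = c(rep(c(1, 0), c(6, 14)), rep(0, 15)))
  f <- estimate_frequencies(d, "e")
  expect_equal(f$frequency[f$group_key == "g1"], 0.30)
  expect_equal(f$frequency[f$group_key == "g2"], 0)
  expect_equal(f$n, c(20L, 15L))
})

test_that("frequency estimates recover true prevalences within binomial error", {
  sim <- simulate_grouped_cohort(rep(500, 20),
                                 withr::with_seed(2, rbeta(20, 2, 5)),
                                 seed = 9)
  d <- add_group_key(sim$records, "standard")
  f <- estimate_frequencies(d, "exposure")
  f <- dplyr::left_join(f, sim$truth, by = "group_key")
  # 95% binomial envelope at n = 500 and p ~ Beta(2,5) is under +/- 0.06
  expect_true(all(abs(f$frequency - f$prevalence) < 0.06))
})

test_that("thresholding is strict: a frequency equal to the cut-off is unexposed", {
  freq <- tibble::tibble(group_key = c("a", "b"), frequency = c(0.30, 0.31))
  d <- tibble::tibble(group_key = c("a", "b", "zz"))
  out <- apply_frequencies(d, freq, threshold = 0.30)
  expect_equal(out$predicted[1:2], c(0L, 1L))
  expect_true(is.na(out$predicted[3]))  # unassigned group, not an error
  # threshold 1 predicts nobody exposed
  out1 <- apply_frequencies(d[1:2, ], freq, threshold = 1)
  expect_equal(out1$predicted, c(0L, 0L))
})

test_that("the scan covers the 21-point grid with monotone sensitivity/specificity", {
  withr::with_seed(11, {
    scores <- sample(seq(0, 1, 0.05), 400, replace = TRUE)
    truth <- rbinom(400, 1, pmin(pmax(scores, 0.05), 0.95))
  })
  scan <- threshold_scan(scores, truth)
  expect_equal(nrow(scan), 21L)
  expect_equal(scan$threshold, threshold_grid())
  expect_true(all(diff(scan$sensitivity) <= 1e-12))
  expect_true(all(diff(scan$specificity) >= -1e-12))
  expect_gte(scan$sensitivity[1], max(scan$sensitivity))
})

test_that("threshold selection maximizes F1 with specificity then threshold tie-breaks", {
  scan <- tibble::tibble(threshold = c(0.1, 0.2, 0.3, 0.4),
                         f1 = c(0.2, 0.5, 0.5, 0.1),
                         specificity = c(0.9, 0.6, 0.8, 0.95))
  expect_equal(select_threshold(scan), 0.3)
  scan2 <- tibble::tibble(threshold = c(0.1, 0.2), f1 = c(0.9, 0.3),
                          specificity = c(0.1, 0.99))
  expect_equal(select_threshold(scan2), 0.1)
  withr::with_seed(21, {
    for (i in 1:200) {
      s <- tibble::tibble(
        threshold = threshold_grid(),
        f1 = sample(seq(0, 1, 0.25), 21, replace = TRUE),
        specificity = sample(seq(0, 1, 0.25), 21, replace = TRUE)
      )
      expect_equal(select_threshold(s), oracle_select(s))
    }
  })
})

test_that("perfectly group-determined exposure reaches AUC = 1 and kappa = 1", {
  sep <- make_separable_cohort(n = 1000, n_groups = 10, gap = 1, seed = 6)
  d <- add_group_key(sep$records, "standard")
  d <- split_cohort(d, 0.7, seed = 2)
  learning <- dplyr::filter(d, split == "learning")
  test <- dplyr::filter(d, split == "test")
  f <- estimate_frequencies(learning, "exposure")
  sc <- apply_frequencies(test, f)
  scan <- threshold_scan(sc$frequency, sc$exposure)
  expect_equal(max(scan$kappa), 1)
  perf <- evaluate_column(sc$frequency, sc$exposure, select_threshold(scan))
  expect_equal(perf$auc, 1)
  expect_equal(perf$kappa, 1)
})

test_that("identical constant scores give AUC 0.5", {
  expect_equal(evaluate_column(rep(0.4, 50), rep(c(0, 1), 25), 0.5)$auc, 0.5)
})

test_that("build_jem produces one column and report per exposure, reproducibly", {
  sim <- generate_cohort(cohort_config(n = 4000, seed = 13))
  jem <- build_jem(sim$records, seed = 5)
  expect_s3_class(jem, "jem")
  expect_equal(nrow(jem$performance), 24L)
  expect_equal(sort(unique(jem$table$exposure)), sort(exposure_specs()$exposure))
  expect_true(all(jem$table$n > 10))
  # frequency * n is a count
  expect_equal(jem$table$frequency * jem$table$n, round(jem$table$n_exposed),
               tolerance = 1e-9)
  # bit-identical rebuild under the same seed
  jem2 <- build_jem(sim$records, seed = 5)
  expect_identical(jem$table, jem2$table)
  expect_identical(jem$performance, jem2$performance)
  expect_identical(jem$scans, jem2$scans)
  # predictions at threshold 0 mark exactly the positive-frequency groups
  one <- dplyr::filter(jem$table, exposure == "shift_work")
  at0 <- apply_frequencies(dplyr::select(one, group_key),
                           dplyr::select(one, group_key, frequency),
                           threshold = 0)
  expect_equal(at0$predicted, as.integer(one$frequency > 0))
  expect_true(all(one$exposed %in% c(0L, 1L)))
})

test_that("the simplified variant coarsens: fewer, larger groups", {
  sim <- generate_cohort(cohort_config(n = 4000, seed = 14))
  std <- build_jem(sim$records, seed = 5)
  simp <- build_jem(sim$records, variant = "simplified", seed = 5)
  for (e in c("shift_work", "infectious_risks")) {
    n_std <- sum(std$table$exposure == e)
    n_simp <- sum(simp$table$exposure == e)
    expect_lte(n_simp, n_std)
  }
  expect_false("naf" %in% names(simp$table))
})

test_that("full-dataset frequencies track learning-sample frequencies", {
  sim <- generate_cohort(cohort_config(n = 8000, seed = 15))
  d <- add_group_key(dichotomize_exposures(sim$records), "standard")
  d <- split_cohort(d, 0.7, seed = 3)
  cc <- complete_case(dplyr::filter(d, groupable), "shift_work")
  ex <- exclude_small_groups(cc)
  f_learn <- estimate_frequencies(
    dplyr::filter(ex$records, split == "learning"), "shift_work")
  f_full <- estimate_frequencies(ex$records, "shift_work")
  j <- dplyr::inner_join(f_learn, f_full, by = "group_key",
                         suffix = c("_l", "_f"))
  # per group the deviation is O(n^-1/2); allow 4 binomial standard errors
  dev <- abs(j$frequency_l - j$frequency_f)
  bound <- 4 * sqrt(pmax(j$frequency_f * (1 - j$frequency_f), 0.25 / j$n_f) /
                      pmax(j$n_l, 1))
  expect_true(mean(dev <= bound + 1e-9) > 0.95)
})

test_that("the selected threshold tracks the generative separation point", {
  # two-point design with strata at 0.2 / 0.8: every grid cut inside the gap
  # yields identical predictions, so the tie-breaks push the selection to the
  # grid point just below the upper stratum prevalence
  sep <- make_separable_cohort(n = 6000, n_groups = 10, gap = 0.6, seed = 20)
  cmp <- compare_methods(sep$records, "exposure", methods = "frequency",
                         specs = binary_spec(), seed = 21, n_boot = 50)
  expect_lte(abs(cmp$optimal_cutoff - 0.75), 0.05 + 1e-9)
})
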