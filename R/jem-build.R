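#' Threshold grid for dichotomizing group frequencies
#'
#' The scan grid runs from 0 to 1 in increments of 0.05 (21 points).
#'
#' @return Numeric vector of length 21.
#' @export
threshold_grid <- function() round(seq(0, 1, by = 0.05), 10)

#' Randomly split a cohort into learning and test sets
#'
#' Simple random (unstratified) partition; the learning set holds
#' `round(learning_fraction * N)` records. Reproducible for a fixed seed.
#'
#' @param data Cohort tibble (>= 2 rows).
#' @param learning_fraction Fraction allocated to the learning set, strictly
#'   between 0 and 1; default 0.70.
#' @param seed Integer seed controlling the draw.
#' @return `data` with an added character column `split`
#'   (`"learning"`/`"test"`).
#' @export
split_cohort <- function(data, learning_fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(data), nrow(data) >= 2,
            learning_fraction > 0, learning_fraction < 1)
  n <- nrow(data)
  n_learn <- round(learning_fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_learn))
  data$split <- "test"
  data$split[idx] <- "learning"
  as_tibble(data)
}

#' Drop occupational groups too small for stable estimates
#'
#' Groups with 10 or fewer complete-case members for the exposure at hand
#' are excluded from that exposure's analysis. Sizes are counted on the full
#' (pre-split) dataset, and exclusion is per exposure: a group may be
#' retained for one exposure and excluded for another with more missingness.
#'
#' @param data Cohort tibble with `group_key`, already complete-case
#'   restricted for the exposure under analysis.
#' @param min_size Minimum complete-case members for retention (default 11,
#'   i.e. groups of <= 10 are excluded).
#' @return A list with `records` (rows of `data` in retained groups) and
#'   `groups` (tibble `group_key`, `n`, `retained`). Errors with class
#'   `jembuild_no_groups` when no group survives.
#' @export
exclude_small_groups <- function(data, min_size = 11L) {
  stopifnot("group_key" %in% names(data))
  sizes <- count(filter(data, !is.na(.data$group_key)), .data$group_key, name = "n")
  sizes$retained <- sizes$n >= min_size
  if (!any(sizes$retained)) {
    abort("No occupational group reaches the minimum size.",
          class = "jembuild_no_groups")
  }
  keep <- sizes$group_key[sizes$retained]
  list(
    records = filter(data, .data$group_key %in% keep),
    groups = arrange(sizes, desc(.data$n))
  )
}

#' Estimate per-group exposure frequencies
#'
#' The JEM exposure assessment for a group is the observed fraction of its
#' (complete-case) members reporting the exposure, computed on the learning
#' sample only during validation and on the full dataset for the final JEM.
#'
#' @param data Learning-sample tibble with `group_key` and a dichotomized
#'   exposure column (no missing values for that exposure).
#' @param exposure Exposure column name.
#' @return Tibble with `group_key`, `n`, `n_exposed`, `frequency`.
#' @export
estimate_frequencies <- function(data, exposure) {
  stopifnot(all(c("group_key", exposure) %in% names(data)))
  out <- summarise(
    group_by(data, .data$group_key),
    n = n(),
    n_exposed = sum(.data[[exposure]]),
    frequency = .data$n_exposed / .data$n,
    .groups = "drop"
  )
  arrange(out, .data$group_key)
}

#' Assign group frequencies and thresholded exposure to individuals
#'
#' Joins each individual to its group's estimated frequency and, when a
#' threshold is given, predicts exposure iff the frequency strictly exceeds
#' it ("exceeded" read literally, so threshold 1 predicts nobody exposed).
#' Individuals in groups absent from `frequencies` get `NA` (unassigned).
#'
#' @param data Tibble of individuals with `group_key`.
#' @param frequencies Output of [estimate_frequencies()].
#' @param threshold Optional dichotomization threshold in \[0, 1\].
#' @return `data` with added `frequency` and (if `threshold` given)
#'   integer `predicted` columns.
#' @export
apply_frequencies <- function(data, frequencies, threshold = NULL) {
  out <- left_join(data, select(frequencies, "group_key", "frequency"),
                   by = "group_key")
  if (!is.null(threshold)) {
    stopifnot(threshold >= 0, threshold <= 1)
    out$predicted <- as.integer(out$frequency > threshold)
  }
  as_tibble(out)
}

#' Scan the threshold grid on the test sample
#'
#' For every threshold in the 0--1 step-0.05 grid, dichotomizes the group
#' frequencies carried by the test individuals and computes kappa, F1,
#' sensitivity and specificity against self-report.
#'
#' @param scores Numeric vector of group frequencies assigned to test
#'   individuals.
#' @param truth Binary vector of their self-reported exposure.
#' @param grid Thresholds to scan; default [threshold_grid()].
#' @return Tibble with one row per threshold and columns `threshold`,
#'   `kappa`, `f1`, `sensitivity`, `specificity`.
#' @export
threshold_scan <- function(scores, truth, grid = threshold_grid()) {
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  purrr::map_dfr(grid, function(thr) {
    bind_cols(tibble(threshold = thr),
              classification_metrics(as.integer(scores > thr), truth))
  })
}

#' Select the optimal threshold from a scan
#'
#' The optimal cut-off maximizes F1; among F1-equivalent cut-offs the one
#' with the highest specificity is chosen (minimizing false positives), and
#' any residual tie goes to the highest threshold so selection is
#' deterministic.
#'
#' @param scan Tibble from [threshold_scan()] (columns `threshold`, `f1`,
#'   `specificity`).
#' @return The selected threshold (scalar).
#' @export
select_threshold <- function(scan) {
  stopifnot(nrow(scan) > 0)
  i <- order(-scan$f1, -scan$specificity, -scan$threshold)[1]
  scan$threshold[i]
}

#' Validate one JEM column on the test sample
#'
#' AUC is computed on the continuous group frequencies (tie-corrected), so
#' it does not depend on the chosen cut-off; kappa, F1, sensitivity and
#' specificity are computed at the selected threshold. The binarized AUC
#' (sensitivity + specificity)/2 is included as a diagnostic.
#'
#' @inheritParams threshold_scan
#' @param threshold The selected dichotomization threshold.
#' @return One-row tibble: `auc`, `optimal_cutoff`, `kappa`, `f1`,
#'   `specificity`, `sensitivity`, `auc_binarized`.
#' @export
evaluate_column <- function(scores, truth, threshold) {
  m <- classification_metrics(as.integer(scores > threshold), truth)
  tibble(
    auc = auc_roc(scores, truth),
    optimal_cutoff = threshold,
    kappa = m$kappa,
    f1 = m$f1,
    specificity = m$specificity,
    sensitivity = m$sensitivity,
    auc_binarized = (m$sensitivity + m$specificity) / 2
  )
}

normalize_cohort_codes <- function(data) {
  stopifnot("pcs" %in% names(data))
  pcs <- tolower(trimws(as.character(data$pcs)))
  pcs[!is.na(pcs) & nchar(pcs) != 4L] <- NA_character_
  data$pcs <- pcs
  if ("naf" %in% names(data)) {
    naf <- tolower(gsub("[. ]", "", as.character(data$naf)))
    naf[!is.na(naf) & (nchar(naf) < 1L | nchar(naf) > 5L)] <- NA_character_
    data$naf <- naf
  }
  data
}

#' Build and internally validate a job-exposure matrix
#'
#' The end-to-end group-based frequency method. The cohort is randomly split
#' 70/30 once; then, for each exposure: records missing that exposure are
#' dropped (complete case), occupational groups with <= 10 complete-case
#' members are excluded, per-group exposure frequencies are estimated on the
#' learning sample, the 21-point threshold grid is scanned on the test
#' sample, the F1-optimal cut-off (specificity tie-break) is selected, and
#' performance (AUC on continuous frequencies; kappa/F1/sensitivity/
#' specificity at the cut-off) is reported. The published-style JEM column
#' is then recomputed from the full dataset with the selected cut-off
#' carried over.
#'
#' @param data Cohort tibble: columns `pcs`, `naf` (codes; normalized
#'   internally, invalid codes become ungroupable), optionally `public` and
#'   `large` (logical, for the alternative variant), and one raw-scale
#'   column per exposure in `specs`.
#' @param specs Exposure specification tibble; default [exposure_specs()].
#'   Only exposures present as columns in `data` are built.
#' @param variant Group keying: `"standard"` (occupation x sector),
#'   `"simplified"` (occupation only) or `"alternative"` (plus establishment
#'   stratum).
#' @param learning_fraction,seed Passed to [split_cohort()].
#' @param min_group_size Minimum complete-case group size (default 11).
#'
#' @return An object of class `jem` with elements `table` (the JEM: one row
#'   per group x exposure with `n`, `frequency`, `threshold`, `exposed`),
#'   `performance` (one row per exposure), `scans` (the full threshold
#'   grids), `groups` (per-exposure group retention), `failures`, and
#'   provenance fields (`variant`, `seed`, `learning_fraction`,
#'   `n_records`, `built`). Use [tidy()] / [glance()] / [autoplot()].
#' @export
build_jem <- function(data, specs = exposure_specs(),
                      variant = c("standard", "simplified", "alternative"),
                      learning_fraction = 0.7, seed = 1L,
                      min_group_size = 11L) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(data))
  exposures <- intersect(specs$exposure, names(data))
  if (length(exposures) == 0) {
    abort("No exposure column from `specs` found in `data`.",
          class = "jembuild_no_exposures")
  }
  data <- normalize_cohort_codes(data)
  data <- add_group_key(data, variant)
  data <- dichotomize_exposures(data, specs)
  data <- split_cohort(data, learning_fraction, seed)
  grouped <- filter(data, .data$groupable)

  res <- purrr::map(exposures, function(e) {
    tryCatch({
      cc <- complete_case(grouped, e)
      ex <- exclude_small_groups(cc, min_size = min_group_size)
      learning <- filter(ex$records, .data$split == "learning")
      test <- filter(ex$records, .data$split == "test")
      freq <- estimate_frequencies(learning, e)
      scored <- apply_frequencies(test, freq)
      unassigned <- sum(is.na(scored$frequency))
      scored <- filter(scored, !is.na(.data$frequency))
      scan <- threshold_scan(scored$frequency, scored[[e]])
      thr <- select_threshold(scan)
      perf <- evaluate_column(scored$frequency, scored[[e]], thr)
      full <- estimate_frequencies(ex$records, e)
      full$threshold <- thr
      full$exposed <- as.integer(full$frequency > thr)
      groups_tab <- ex$groups
      list(
        table = bind_cols(tibble(exposure = e), full),
        performance = bind_cols(
          tibble(exposure = e), perf,
          tibble(
            n_groups = sum(groups_tab$retained),
            n_retained = nrow(ex$records),
            n_complete = nrow(cc),
            n_test = nrow(scored),
            n_unassigned = unassigned
          )
        ),
        scan = bind_cols(tibble(exposure = e), scan),
        groups = bind_cols(tibble(exposure = e), groups_tab),
        failure = NULL
      )
    }, error = function(err) {
      list(table = NULL, performance = NULL, scan = NULL, groups = NULL,
           failure = tibble(exposure = e, error = conditionMessage(err)))
    })
  })

  table <- purrr::list_rbind(purrr::map(res, "table"))
  if (nrow(table) > 0) table <- decompose_group_key(table, variant)
  structure(
    list(
      table = table,
      performance = purrr::list_rbind(purrr::map(res, "performance")),
      scans = purrr::list_rbind(purrr::map(res, "scan")),
      groups = purrr::list_rbind(purrr::map(res, "groups")),
      failures = purrr::list_rbind(purrr::map(res, "failure")),
      variant = variant,
      learning_fraction = learning_fraction,
      seed = seed,
      min_group_size = min_group_size,
      n_records = nrow(data),
      n_ungroupable = sum(!data$groupable),
      built = format(Sys.Date())
    ),
    class = "jem"
  )
}

decompose_group_key <- function(table, variant) {
  parts <- stringr::str_split_fixed(table$group_key, stringr::fixed("|"), 3)
  table$pcs <- parts[, 1]
  if (variant != "simplified") table$naf <- parts[, 2]
  if (variant == "alternative") {
    st <- stringr::str_split_fixed(parts[, 3], stringr::fixed("."), 2)
    table$sector_type <- st[, 1]
    table$size_class <- st[, 2]
  }
  dplyr::relocate(table, dplyr::any_of(c("exposure", "pcs", "naf",
                                         "sector_type", "size_class")))
}

#' @export
print.jem <- function(x, ...) {
  cat(sprintf("<jem> %s variant | %d records | seed %s\n",
              x$variant, x$n_records, format(x$seed)))
  cat(sprintf("  %d exposure columns, %d group x exposure cells\n",
              nrow(x$performance), nrow(x$table)))
  if (nrow(x$performance) > 0) {
    cat(sprintf("  AUC %.3f-%.3f | kappa %.3f-%.3f\n",
                min(x$performance$auc), max(x$performance$auc),
                min(x$performance$kappa), max(x$performance$kappa)))
  }
  if (!is.null(x$failures) && nrow(x$failures) > 0) {
    cat(sprintf("  %d exposure(s) failed: %s\n", nrow(x$failures),
                paste(x$failures$exposure, collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn build_jem `tidy()` returns the JEM table (group x exposure
#'   rows with `n`, `frequency`, `threshold`, `exposed`).
#' @param x A `jem` object.
#' @param ... Unused.
#' @method tidy jem
#' @export
tidy.jem <- function(x, ...) x$table

#' @describeIn build_jem `glance()` returns the per-exposure performance
#'   report (AUC, optimal cut-off, kappa, F1, specificity, sensitivity).
#' @method glance jem
#' @export
glance.jem <- function(x, ...) x$performance
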