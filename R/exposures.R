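#' Default exposure specifications
#'
#' The 24 self-reported occupational exposures the JEM covers, spanning
#' organizational, biomechanical, physical, chemical/biological and
#' psychosocial factors. Each row records the response scale, the
#' dichotomization cut-off, and two cohort-level quantities used by the
#' synthetic generator: the marginal prevalence of the dichotomized exposure
#' and the proportion of missing responses.
#'
#' Scales: `binary` (0/1 as reported); `likert4` (1 = never or nearly never
#' ... 4 = always or nearly always; exposed at >= 3, i.e. "often" or more);
#' `effort0_3` (0 = sedentary ... 3 = heavy efforts; only heavy efforts count
#' as exposed); `borg6_20` (Borg Rating of Perceived Exertion, 6--20;
#' exposed at >= 13, intense physical effort); `eri_score` (effort--reward
#' imbalance ratio; exposed at >= 1.5).
#'
#' @return A 24-row tibble with columns `exposure`, `domain`, `scale`,
#'   `cutoff`, `prevalence`, `missingness`.
#' @examples
#' exposure_specs()
#' @export
exposure_specs <- function() {
  tibble::tribble(
    ~exposure,                   ~domain,          ~scale,      ~cutoff, ~prevalence, ~missingness,
    "late_hours",                "organizational", "binary",    NA,      0.100,       0.009,
    "early_hours",               "organizational", "binary",    NA,      0.075,       0.009,
    "sleepless_nights",          "organizational", "binary",    NA,      0.102,       0.006,
    "long_working_hours",        "organizational", "binary",    NA,      0.252,       0.008,
    "weekly_rest_lt48h",         "organizational", "binary",    NA,      0.158,       0.013,
    "shift_work",                "organizational", "binary",    NA,      0.214,       0.014,
    "saturday_work",             "organizational", "binary",    NA,      0.228,       0.007,
    "sunday_work",               "organizational", "binary",    NA,      0.160,       0.008,
    "time_constrained_job",      "biomechanical",  "binary",    NA,      0.025,       0.008,
    "repetitive_work",           "biomechanical",  "likert4",   3,       0.263,       0.037,
    "physically_difficult_work", "biomechanical",  "binary",    NA,      0.191,       0.015,
    "physical_effort_at_work",   "biomechanical",  "effort0_3", 3,       0.403,       0.041,
    "carry_heavy_loads",         "biomechanical",  "binary",    NA,      0.248,       0.013,
    "carry_heavy_loads_25kg",    "biomechanical",  "likert4",   3,       0.137,       0.041,
    "arms_above_shoulder",       "biomechanical",  "likert4",   3,       0.092,       0.023,
    "kneel_or_squat",            "biomechanical",  "likert4",   3,       0.350,       0.016,
    "intense_physical_effort",   "biomechanical",  "borg6_20",  13,      0.507,       0.024,
    "noise_pollution",           "physical",       "binary",    NA,      0.091,       0.006,
    "noisy_tools",               "physical",       "binary",    NA,      0.064,       0.008,
    "ionizing_radiation",        "physical",       "binary",    NA,      0.129,       0.047,
    "formaldehyde",              "bio_chemical",   "binary",    NA,      0.028,       0.039,
    "infectious_risks",          "bio_chemical",   "binary",    NA,      0.600,       0.034,
    "live_dead_animals",         "bio_chemical",   "binary",    NA,      0.040,       0.019,
    "effort_reward_imbalance",   "psychosocial",   "eri_score", 1.5,     0.155,       0.036
  )
}

scale_range <- function(scale) {
  switch(scale,
    binary    = c(0, 1),
    likert4   = c(1, 4),
    effort0_3 = c(0, 3),
    borg6_20  = c(6, 20),
    eri_score = c(0.25, 4),
    abort(sprintf("Unknown scale '%s'.", scale), class = "jembuild_bad_scale")
  )
}

#' Dichotomize a raw exposure response
#'
#' Maps mixed-scale responses onto a single exposed/unexposed contract:
#' binary responses pass through; 4-point Likert responses of "often" or
#' "always or nearly always" (>= 3) indicate exposure; the 0--3 physical
#' effort scale counts only heavy efforts (= 3); Borg RPE >= 13 indicates
#' intense physical effort; an effort--reward imbalance score >= 1.5
#' indicates high imbalance. Missing responses stay missing.
#'
#' @param value Numeric vector of raw responses (may contain `NA`).
#' @param scale One of `"binary"`, `"likert4"`, `"effort0_3"`, `"borg6_20"`,
#'   `"eri_score"`.
#' @param cutoff Optional cut-off overriding the scale default.
#'
#' @return Integer 0/1 vector with `NA` preserved.
#' @examples
#' dichotomize(c(2, 3, NA), "likert4")
#' dichotomize(12:14, "borg6_20")
#' @export
dichotomize <- function(value, scale, cutoff = NULL) {
  rng <- scale_range(scale)
  out_of_range <- !is.na(value) & (value < rng[1] | value > rng[2])
  if (any(out_of_range)) {
    abort(
      sprintf("Value(s) outside the %s scale [%s, %s]: %s.", scale, rng[1], rng[2],
              paste(head(unique(value[out_of_range]), 5), collapse = ", ")),
      class = "jembuild_out_of_range"
    )
  }
  res <- switch(scale,
    binary    = value,
    likert4   = as.numeric(value >= (cutoff %||% 3)),
    effort0_3 = as.numeric(value >= (cutoff %||% 3)),
    borg6_20  = as.numeric(value >= (cutoff %||% 13)),
    eri_score = as.numeric(value >= (cutoff %||% 1.5))
  )
  as.integer(res)
}

#' Effort--reward imbalance score
#'
#' Computes Siegrist's short-form effort--reward ratio from the three effort
#' and seven reward items: sum(effort) / (sum(reward) * 3/7). The 3/7 factor
#' corrects for the unequal item counts so a respondent scoring identically
#' on every item gets a ratio of 1. Scores >= 1.5 are conventionally read as
#' high imbalance. Cohorts that ship a precomputed score column should use it
#' directly; this helper is for raw items.
#'
#' @param effort Numeric matrix/data frame with 3 columns (one row per
#'   respondent), or a length-3 vector for a single respondent.
#' @param reward Numeric matrix/data frame with 7 columns, or a length-7
#'   vector.
#'
#' @return Numeric vector of ERI scores. Errors with class
#'   `jembuild_missing_item` when any item is missing.
#' @examples
#' eri_score(c(4, 4, 4), c(1, 1, 1, 1, 1, 1, 1))
#' @export
eri_score <- function(effort, reward) {
  if (is.null(dim(effort))) effort <- matrix(effort, nrow = 1)
  if (is.null(dim(reward))) reward <- matrix(reward, nrow = 1)
  effort <- as.matrix(effort); reward <- as.matrix(reward)
  if (ncol(effort) != 3L || ncol(reward) != 7L) {
    abort("`effort` must have 3 items and `reward` 7 items.",
          class = "jembuild_missing_item")
  }
  if (anyNA(effort) || anyNA(reward)) {
    abort("All 10 ERI items must be present.", class = "jembuild_missing_item")
  }
  rowSums(effort) / (rowSums(reward) * 3 / 7)
}

#' Dichotomize every exposure column of a cohort
#'
#' Applies [dichotomize()] to each exposure named in `specs` that is present
#' in `data`, replacing the raw column with its 0/1 version in place.
#'
#' @param data Cohort tibble with raw exposure columns.
#' @param specs Exposure specification tibble, default [exposure_specs()].
#' @return `data` with the listed exposure columns dichotomized.
#' @export
dichotomize_exposures <- function(data, specs = exposure_specs()) {
  present <- intersect(specs$exposure, names(data))
  for (e in present) {
    row <- specs[specs$exposure == e, ]
    data[[e]] <- dichotomize(data[[e]], row$scale, row$cutoff)
  }
  as_tibble(data)
}

#' Per-exposure complete-case restriction
#'
#' Drops the records whose (dichotomized) response for one exposure is
#' missing. Restriction is always per exposure: a record missing one exposure
#' still contributes to every other exposure's analysis, matching the
#' complete-case convention under which per-exposure analysis Ns differ.
#'
#' @param data Cohort tibble.
#' @param exposure Name of the exposure column.
#' @return The subset of `data` with a non-missing value for `exposure`;
#'   values are never altered, only membership.
#' @export
complete_case <- function(data, exposure) {
  stopifnot(exposure %in% names(data))
  data[!is.na(data[[exposure]]), , drop = FALSE]
}
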