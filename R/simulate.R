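#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a national healthcare-worker cohort: 12 489 workers
#' spread over 31 occupation codes paired with 144 sector codes, a strongly
#' skewed group-size law (a handful of large professions such as nurses
#' dominate, most occupation x sector pairs are small), 24 mixed-scale
#' exposures with realistic marginal prevalences and 0.6--4.7% missingness,
#' and an establishment mix of 53.7% public and 67.6% large (>= 200
#' employees) workplaces.
#'
#' @param n Number of individuals.
#' @param n_pcs Number of distinct occupation codes.
#' @param n_pairs Number of occupation x sector pairings (the potential
#'   occupational groups).
#' @param size_exponent Exponent of the truncated power law governing group
#'   sizes (larger = more skew). The default 1.5 was calibrated once so that
#'   a minority of the pairings exceed 10 members while covering over 90% of
#'   individuals.
#' @param concentration Beta concentration of between-group prevalence
#'   dispersion: per-group prevalences are drawn from
#'   Beta(m*c, (1-m)*c) around each exposure's marginal target m, then
#'   recentred on the logit scale so the size-weighted mean equals m.
#' @param specs Exposure specification tibble (scales, cut-offs, marginal
#'   prevalences, missingness); default [exposure_specs()].
#' @param p_public,p_large Establishment mix probabilities.
#' @param miss_public,miss_large Missingness of the establishment columns.
#' @param p_female Share of women (passenger column; no exposure depends on
#'   it).
#' @param seed Integer seed; every random draw flows from it.
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(n = 12489L, n_pcs = 31L, n_pairs = 144L,
                          size_exponent = 1.5, concentration = 4,
                          specs = exposure_specs(),
                          p_public = 0.537, p_large = 0.676,
                          miss_public = 0.132, miss_large = 0.061,
                          p_female = 0.805, seed = 1L) {
  stopifnot(n > 0, n_pcs > 0, n_pairs >= n_pcs, size_exponent > 0,
            concentration > 0,
            all(specs$prevalence >= 0 & specs$prevalence <= 1),
            all(specs$missingness >= 0 & specs$missingness <= 1))
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic occupation/sector code catalog
#'
#' Produces format-valid occupation codes (4 characters: three nested
#' levels of 1, 2 and 4 characters) and sector codes (1--5 characters,
#' declared depth = length, prefixes consistent), paired so that every
#' occupation is linked to at least one sector. Codes are synthetic: they
#' mimic the shape of PCS-2003 / NAF-2008 codes, not their official content.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per occupation x sector pairing: columns
#'   `pair_id`, `pcs`, `naf`, `naf_depth`.
#' @export
generate_catalog <- function(config = cohort_config()) {
  withr::with_seed(config$seed + 1L, {
    # occupation codes: classes 3-5, categories share prefixes
    pcs <- character(0)
    while (length(pcs) < config$n_pcs) {
      cand <- paste0(sample(3:5, 50, TRUE), sample(1:8, 50, TRUE),
                     sample(1:9, 50, TRUE), sample(letters[1:6], 50, TRUE))
      pcs <- unique(c(pcs, cand))
    }
    pcs <- sort(pcs[seq_len(config$n_pcs)])
    # sector codes: full 5-char codes truncated to a declared depth
    depths <- sample(1:5, config$n_pairs * 3, TRUE,
                     prob = c(0.04, 0.08, 0.13, 0.25, 0.50))
    full <- paste0(sample(7:9, config$n_pairs * 3, TRUE),
                   sample(c("5", "6", "7", "8"), config$n_pairs * 3, TRUE),
                   sample(0:9, config$n_pairs * 3, TRUE),
                   sample(0:3, config$n_pairs * 3, TRUE),
                   sample(letters[c(1, 2, 26)], config$n_pairs * 3, TRUE))
    naf <- unique(substr(full, 1, depths))
    stopifnot(length(naf) >= config$n_pairs)
    naf <- naf[seq_len(config$n_pairs)]
    # each occupation gets >= 1 sector; extras follow a skewed allocation
    owner <- c(seq_len(config$n_pcs),
               sample(seq_len(config$n_pcs), config$n_pairs - config$n_pcs,
                      TRUE, prob = seq_len(config$n_pcs)^-1))
    tibble(
      pair_id = seq_len(config$n_pairs),
      pcs = pcs[owner],
      naf = naf,
      naf_depth = nchar(naf)
    )
  })
}

# recentre group prevalences on the logit scale so their size-weighted mean
# hits the marginal target
calibrate_prevalences <- function(p, w, target) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  if (target <= 0 || target >= 1) return(rep(target, length(p)))
  f <- function(d) sum(w * plogis(qlogis(p) + d)) - target
  d <- uniroot(f, c(-25, 25), tol = 1e-12)$root
  plogis(qlogis(p) + d)
}

# raw-scale response consistent with a latent binary exposure, so that
# dichotomization recovers the generated truth exactly
raw_from_binary <- function(z, scale) {
  n <- length(z)
  switch(scale,
    binary    = z,
    likert4   = ifelse(z == 1, sample(3:4, n, TRUE), sample(1:2, n, TRUE)),
    effort0_3 = ifelse(z == 1, 3L, sample(0:2, n, TRUE)),
    borg6_20  = ifelse(z == 1, sample(13:20, n, TRUE), sample(6:12, n, TRUE)),
    eri_score = ifelse(z == 1, runif(n, 1.5, 4), runif(n, 0.25, 1.499))
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Individuals are assigned to occupation x sector pairings under a
#' truncated power-law size distribution; per-group exposure prevalences
#' are drawn from a Beta distribution around each exposure's marginal
#' target and recentred so the realized marginal matches the target; binary
#' exposure indicators are Bernoulli draws from the group prevalence; raw
#' ordinal/continuous responses (Likert, Borg, effort, ERI) are generated
#' by inverting the dichotomization rule so the binary truth round-trips;
#' missingness is injected completely at random per exposure. Sex and age
#' are passenger columns for realism only.
#'
#' @param config A [cohort_config()].
#' @return A list with `records` (one row per individual: `id`, `pcs`,
#'   `naf`, `public`, `large`, `female`, `age`, 24 raw exposure columns),
#'   `truth` (per group x exposure: `group_key`, `prevalence`, and the
#'   realized group `n`), `catalog`, and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  catalog <- generate_catalog(config)
  withr::with_seed(config$seed, {
    w <- seq_len(config$n_pairs)^(-config$size_exponent)
    w <- w / sum(w)
    pair <- sample.int(config$n_pairs, config$n, TRUE, prob = w)
    sizes <- tabulate(pair, nbins = config$n_pairs)
    w_real <- sizes / config$n
    group_key <- paste(catalog$pcs, catalog$naf, sep = "|")

    records <- tibble(
      id = seq_len(config$n),
      pcs = catalog$pcs[pair],
      naf = catalog$naf[pair],
      public = runif(config$n) < config$p_public,
      large = runif(config$n) < config$p_large,
      female = runif(config$n) < config$p_female,
      age = pmin(pmax(round(stats::rnorm(config$n, 41, 13)), 18L), 69L)
    )
    records$public[runif(config$n) < config$miss_public] <- NA
    records$large[runif(config$n) < config$miss_large] <- NA

    truth_rows <- vector("list", nrow(config$specs))
    for (i in seq_len(nrow(config$specs))) {
      s <- config$specs[i, ]
      m <- s$prevalence
      p <- rbeta(config$n_pairs, m * config$concentration,
                 (1 - m) * config$concentration)
      p <- calibrate_prevalences(p, w_real, m)
      z <- rbinom(config$n, 1, p[pair])
      raw <- raw_from_binary(z, s$scale)
      raw[runif(config$n) < s$missingness] <- NA
      records[[s$exposure]] <- raw
      truth_rows[[i]] <- tibble(
        exposure = s$exposure, group_key = group_key,
        pcs = catalog$pcs, naf = catalog$naf,
        n = sizes, prevalence = p
      )
    }
    truth <- purrr::list_rbind(truth_rows)
    list(records = records, truth = truth, catalog = catalog, config = config)
  })
}

#' Simulate a grouped cohort from explicit sizes and prevalences
#'
#' Low-level generator used in parameter-recovery checks: each group gets a
#' stated size and true exposure prevalence, a distinct occupation code and
#' a distinct sector code, and one binary exposure column.
#'
#' @param sizes Integer vector of group sizes.
#' @param prevalences Numeric vector of per-group true prevalences, same
#'   length.
#' @param exposure Name of the generated binary exposure column.
#' @param seed Integer seed.
#' @return A list with `records` (`id`, `pcs`, `naf`, exposure column) and
#'   `truth` (`group_key`, `pcs`, `naf`, `n`, `prevalence`).
#' @export
simulate_grouped_cohort <- function(sizes, prevalences,
                                    exposure = "exposure", seed = 1L) {
  stopifnot(length(sizes) == length(prevalences),
            all(prevalences >= 0 & prevalences <= 1),
            length(sizes) <= 600)
  k <- length(sizes)
  pcs <- paste0("4", sprintf("%02d", seq_len(k) %% 100),
                letters[(seq_len(k) - 1) %/% 100 + 1])
  naf <- paste0("86", sprintf("%02d", seq_len(k) %% 100),
                letters[(seq_len(k) - 1) %/% 100 + 1])
  g <- rep(seq_len(k), sizes)
  withr::with_seed(seed, {
    z <- rbinom(length(g), 1, prevalences[g])
    list(
      records = tibble(id = seq_along(g), pcs = pcs[g], naf = naf[g]),
      truth = tibble(group_key = paste(pcs, naf, sep = "|"), pcs = pcs,
                     naf = naf, n = as.integer(sizes),
                     prevalence = prevalences)
    ) -> out
    out$records[[exposure]] <- z
    out
  })
}

#' Two-population separable fixture
#'
#' Splits `n_groups` equally sized groups into two strata with true
#' prevalences 1/2 + gap/2 and 1/2 - gap/2. With `gap = 1` exposure is
#' fully determined by group membership (the AUC = 1 limit); with
#' `gap = 0` groups are indistinguishable (AUC = 1/2). The analytic AUC of
#' the two-point score distribution is returned alongside the data as the
#' recovery oracle.
#'
#' @param n Total individuals (split evenly across groups).
#' @param n_groups Number of groups (even; half per stratum).
#' @param gap Prevalence separation in (0, 1\].
#' @param seed Integer seed.
#' @return As [simulate_grouped_cohort()], plus `analytic_auc`.
#' @export
make_separable_cohort <- function(n = 3000L, n_groups = 20L, gap = 0.6,
                                  seed = 1L) {
  stopifnot(gap >= 0, gap <= 1, n_groups %% 2 == 0)
  p_hi <- 0.5 + gap / 2
  p_lo <- 0.5 - gap / 2
  sizes <- rep(n %/% n_groups, n_groups)
  prev <- rep(c(p_hi, p_lo), each = n_groups / 2)
  out <- simulate_grouped_cohort(sizes, prev, seed = seed)
  out$analytic_auc <- two_point_auc(p_hi, p_lo, 0.5)
  out
}

#' Closed-form AUC of a two-point score distribution
#'
#' When individuals carry one of two scores (high-prevalence stratum scored
#' above low-prevalence stratum) the tie-corrected AUC has a closed form
#' from the four stratum x class probabilities.
#'
#' @param p_hi,p_lo True exposure prevalences of the high/low strata.
#' @param w_hi Population share of the high stratum.
#' @return The analytic AUC.
#' @export
two_point_auc <- function(p_hi, p_lo, w_hi = 0.5) {
  w_lo <- 1 - w_hi
  m <- w_hi * p_hi + w_lo * p_lo
  if (m <= 0 || m >= 1) return(NaN)
  pos_hi <- w_hi * p_hi / m
  neg_hi <- w_hi * (1 - p_hi) / (1 - m)
  pos_hi * (1 - neg_hi) + 0.5 * (pos_hi * neg_hi + (1 - pos_hi) * (1 - neg_hi))
}
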