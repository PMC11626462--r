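# Brute-force, from-definition oracles kept deliberately independent of the
# package's implementations.

oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_kappa <- function(t) {
  n <- t$tp + t$fp + t$fn + t$tn
  po <- (t$tp + t$tn) / n
  pe <- ((t$tp + t$fp) * (t$tp + t$fn) + (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  if (pe == 1) return(NaN)
  (po - pe) / (1 - pe)
}

oracle_sens <- function(t) if (t$tp + t$fn == 0) 0 else t$tp / (t$tp + t$fn)
oracle_spec <- function(t) if (t$tn + t$fp == 0) 0 else t$tn / (t$tn + t$fp)
oracle_f1 <- function(t) {
  d <- 2 * t$tp + t$fp + t$fn
  if (d == 0) 0 else 2 * t$tp / d
}

# pairwise enumeration: P(pos > neg) + 0.5 P(tie)
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# naive lexicographic sort: highest F1, then highest specificity, then
# highest threshold
oracle_select <- function(scan) {
  s <- scan[order(scan$f1, scan$specificity, scan$threshold,
                  decreasing = TRUE), ]
  s$threshold[1]
}

random_confusion <- function() {
  repeat {
    t <- list(tp = sample(0:30, 1), fp = sample(0:30, 1),
              fn = sample(0:30, 1), tn = sample(0:30, 1))
    if (t$tp + t$fp + t$fn + t$tn > 0) return(t)
  }
}

# cohort where exposure is keyed to the full occupation x sector pair while
# each occupation spans sectors with opposite prevalences, so collapsing to
# occupation-only (the simplified variant) must lose discrimination
group_keyed_cohort <- function(n_pcs = 10, naf_per_pcs = 4, group_size = 150,
                               p_hi = 0.9, p_lo = 0.1, seed = 1,
                               n_exposures = 1) {
  pcs <- sprintf("4%02da", seq_len(n_pcs))
  enames <- if (n_exposures == 1) "exposure" else paste0("exposure", seq_len(n_exposures))
  rows <- list()
  withr::with_seed(seed, {
    for (i in seq_len(n_pcs)) {
      for (j in seq_len(naf_per_pcs)) {
        p <- if (j <= naf_per_pcs / 2) p_hi else p_lo
        g <- tibble::tibble(
          pcs = rep(pcs[i], group_size),
          naf = rep(sprintf("86%02d%s", i, letters[j]), group_size)
        )
        for (e in enames) g[[e]] <- rbinom(group_size, 1, p)
        rows[[length(rows) + 1L]] <- g
      }
    }
  })
  dplyr::bind_rows(rows)
}

binary_spec <- function(name = "exposure") {
  tibble::tibble(exposure = name, scale = "binary", cutoff = NA_real_,
                 prevalence = 0.5, missingness = 0)
}

# tiny deterministic grids for learner tests
tiny_grids <- function() {
  list(
    tree = tibble::tibble(maxdepth = 8L, minbucket = 5L),
    forest = tibble::tibble(num_trees = 100L, mtry_rule = "sqrt"),
    boosted = tibble::tibble(max_depth = 2L, eta = 0.3, nrounds = 50L)
  )
}
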