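#' Cross-tabulate binary predictions against self-report
#'
#' Builds the 2x2 confusion table with "exposed" (1) as the positive class.
#'
#' @param pred,truth Binary (0/1 or logical) vectors of equal length with no
#'   missing values.
#' @return An object of class `confusion_table`: a named list with integer
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_table(c(1, 0, 1), c(1, 0, 0))
#' @export
confusion_table <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have equal length.",
          class = "jembuild_length_mismatch")
  }
  if (length(pred) == 0 || anyNA(pred) || anyNA(truth)) {
    abort("`pred` and `truth` must be non-empty with no missing values.",
          class = "jembuild_length_mismatch")
  }
  pred <- as.integer(as.logical(pred))
  truth <- as.integer(as.logical(truth))
  structure(
    list(
      tp = sum(pred == 1L & truth == 1L),
      fp = sum(pred == 1L & truth == 0L),
      fn = sum(pred == 0L & truth == 1L),
      tn = sum(pred == 0L & truth == 0L)
    ),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("exposed", "unexposed"),
                              pred = c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

as_confusion <- function(x) {
  if (inherits(x, "confusion_table")) return(x)
  stopifnot(is.list(x), all(c("tp", "fp", "fn", "tn") %in% names(x)))
  structure(x[c("tp", "fp", "fn", "tn")], class = "confusion_table")
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two binary ratings:
#' kappa = (p_o - p_e) / (1 - p_e), with p_o the observed agreement and p_e
#' the agreement expected from the marginal totals. Here it measures the
#' strength of agreement between JEM-assigned and self-reported exposure.
#' When p_e = 1 (both margins degenerate) kappa is undefined and `NaN` is
#' returned.
#'
#' @param x A `confusion_table` (or a list with `tp`, `fp`, `fn`, `tn`).
#' @return Kappa in \[-1, 1\], or `NaN` when undefined.
#' @examples
#' cohen_kappa(confusion_table(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' @export
cohen_kappa <- function(x) {
  x <- as_confusion(x)
  n <- x$tp + x$fp + x$fn + x$tn
  stopifnot(n > 0)
  po <- (x$tp + x$tn) / n
  pe <- ((x$tp + x$fp) / n) * ((x$tp + x$fn) / n) +
        ((x$fn + x$tn) / n) * ((x$fp + x$tn) / n)
  if (pe == 1) return(NaN)
  (po - pe) / (1 - pe)
}

#' Sensitivity, specificity and F1-score
#'
#' `sensitivity()` is tp/(tp+fn), `specificity()` tn/(tn+fp) and
#' `f1_score()` 2tp/(2tp+fp+fn). A metric whose denominator is zero is
#' defined as 0; in particular a threshold predicting nobody exposed scores
#' F1 = 0 and can never win an F1-maximizing threshold scan.
#'
#' @param x A `confusion_table` (or a list with `tp`, `fp`, `fn`, `tn`).
#' @return A number in \[0, 1\].
#' @examples
#' t <- confusion_table(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' c(sensitivity(t), specificity(t), f1_score(t))
#' @export
sensitivity <- function(x) {
  x <- as_confusion(x)
  safe_ratio(x$tp, x$tp + x$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(x) {
  x <- as_confusion(x)
  safe_ratio(x$tn, x$tn + x$fp)
}

#' @rdname sensitivity
#' @export
f1_score <- function(x) {
  x <- as_confusion(x)
  safe_ratio(2 * x$tp, 2 * x$tp + x$fp + x$fn)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Area under the ROC curve with tie correction
#'
#' Computes AUC as the tie-corrected Mann--Whitney probability
#' P(score_pos > score_neg) + 0.5 P(score_pos = score_neg), via midranks.
#' This equals the trapezoidal area under the empirical ROC curve and is the
#' right convention here: many individuals share one group frequency, so
#' heavily tied scores are the normal case, not an edge case.
#'
#' @param scores Numeric vector of continuous scores (e.g. group exposure
#'   frequencies assigned to individuals).
#' @param truth Binary vector of observed exposure, same length.
#' @return AUC in \[0, 1\]. Errors with class `jembuild_degenerate_truth`
#'   when only one class is present.
#' @examples
#' auc_roc(c(.9, .8, .8, .1), c(1, 1, 0, 0))
#' @export
auc_roc <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    abort("`scores` and `truth` must have equal length.",
          class = "jembuild_length_mismatch")
  }
  if (anyNA(scores) || anyNA(truth)) {
    abort("Missing values are not allowed.", class = "jembuild_length_mismatch")
  }
  truth <- as.integer(as.logical(truth))
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0 || n_neg == 0) {
    abort("`truth` must contain both classes.",
          class = "jembuild_degenerate_truth")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Interpretation band for a kappa value
#'
#' Conventional agreement bands: poor (0--0.20), fair (0.21--0.40), moderate
#' (0.41--0.60), good (0.61--0.80), excellent (0.81--1). Negative kappa maps
#' to poor. Band edges follow the printed two-decimal convention, so 0.20 is
#' poor and 0.21 is fair.
#'
#' @param kappa Numeric vector in \[-1, 1\].
#' @return Character vector of band labels.
#' @examples
#' kappa_band(c(0.556, 0.289, 0.20, 0.21))
#' @export
kappa_band <- function(kappa) {
  stopifnot(all(kappa >= -1 & kappa <= 1, na.rm = TRUE))
  br <- c(-1, 0.205, 0.405, 0.605, 0.805, 1)
  labs <- c("poor", "fair", "moderate", "good", "excellent")
  as.character(cut(round(kappa, 2), breaks = br, labels = labs,
                   include.lowest = TRUE))
}

#' All threshold-scan metrics for one prediction
#'
#' Convenience wrapper returning kappa, F1, sensitivity and specificity of a
#' binary prediction in one row.
#'
#' @inheritParams confusion_table
#' @return A one-row tibble with columns `kappa`, `f1`, `sensitivity`,
#'   `specificity`.
#' @export
classification_metrics <- function(pred, truth) {
  ct <- confusion_table(pred, truth)
  tibble(
    kappa = cohen_kappa(ct),
    f1 = f1_score(ct),
    sensitivity = sensitivity(ct),
    specificity = specificity(ct)
  )
}
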