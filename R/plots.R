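#' Plot per-exposure JEM performance
#'
#' Dot plot of the validation metrics (AUC, kappa, F1, sensitivity,
#' specificity) per exposure, ordered by AUC.
#'
#' @param object A `jem` object.
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot jem
#' @export
autoplot.jem <- function(object, metrics = c("auc", "kappa"), ...) {
  perf <- object$performance
  stopifnot(nrow(perf) > 0, all(metrics %in% names(perf)))
  long <- tidyr::pivot_longer(
    select(perf, "exposure", all_of(metrics)),
    -"exposure", names_to = "metric", values_to = "value"
  )
  ord <- perf$exposure[order(perf$auc)]
  long$exposure <- factor(long$exposure, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$exposure,
                                     colour = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL,
                  title = sprintf("JEM internal validity (%s variant)",
                                  object$variant)) +
    ggplot2::theme_minimal()
}

#' Forest plot of method comparison
#'
#' One row per exposure, one point (with bootstrap interval) per method:
#' the standard visual check that the group-based frequency method and the
#' tree-based learners offer similar discriminatory power.
#'
#' @param object A `jem_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot jem_comparison
#' @export
autoplot.jem_comparison <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$auc, y = .data$exposure,
                    colour = .data$method)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$auc_lo, xmax = .data$auc_hi),
      position = ggplot2::position_dodge(width = 0.6), size = 0.3
    ) +
    ggplot2::labs(x = "AUC (test set, bootstrap 95% interval)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a threshold scan
#'
#' Metric trajectories across the 21-point dichotomization grid for one
#' exposure, with the selected cut-off marked.
#'
#' @param jem A `jem` object.
#' @param exposure Exposure name.
#' @return A ggplot object.
#' @export
plot_threshold_scan <- function(jem, exposure) {
  stopifnot(inherits(jem, "jem"), exposure %in% jem$scans$exposure)
  scan <- filter(jem$scans, .data$exposure == !!exposure)
  thr <- jem$performance$optimal_cutoff[jem$performance$exposure == exposure]
  long <- tidyr::pivot_longer(scan, c("kappa", "f1", "sensitivity",
                                      "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(title = exposure, x = "threshold", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
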