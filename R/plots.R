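#' Distance histogram of a scored sample
#'
#' Frequency histogram of the measured inter-structure distances of a
#' sample's two-structure cells, with the split threshold drawn as a dashed
#' line.
#'
#' @param cell_scores Output of [score_cells()].
#' @param config The [scoring_config()] used for scoring (supplies bin
#'   width and threshold).
#' @return A ggplot.
#' @export
plot_distance_histogram <- function(cell_scores, config = scoring_config()) {
  d <- cell_scores[!is.na(cell_scores$score_distance_um), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score_distance_um)) +
    ggplot2::geom_histogram(binwidth = config$histogram_bin_um,
                            boundary = 0, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = config$split_threshold_um,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "inter-structure distance (µm)", y = "cells",
                  title = sprintf("%.1f%% split (> %.1f µm)",
                                  100 * mean(d$split),
                                  config$split_threshold_um)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ccs_group_comparison
#' @export
autoplot.ccs_group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "% C/C splitting") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @method autoplot ccs_roc
#' @export
autoplot.ccs_roc <- function(object, ...) {
  curve <- tidy(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC c-statistic = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Paired vehicle/MLi2 splitting plot
#'
#' Line plot connecting each subject's vehicle and MLi2 percent splitting,
#' the standard display of inhibitor reversal.
#'
#' @param data Subject-score tibble with `subject_id`, `condition`,
#'   `pct_split` (and optionally `group` for facetting).
#' @return A ggplot.
#' @export
plot_mli2_pairs <- function(data) {
  data$condition <- factor(data$condition, levels = c("vehicle", "MLi2"))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$condition,
                                          y = .data$pct_split,
                                          group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "% C/C splitting") +
    ggplot2::theme_minimal()
  if ("group" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~group)
  }
  p
}
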