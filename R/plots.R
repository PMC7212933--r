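# ggplot2 figures from the exported plot data: calibration plots, forest
# plots, ROC-space summaries.

#' Calibration plot
#'
#' Mean predicted risk against observed MDI proportion per risk bin, with
#' the ideal diagonal; faceted by study when several are present.
#'
#' @param x A `picnicc_performance` table (uses its `"calibration"`
#'   attribute) or a calibration-bin tibble from
#'   [calibration_plot_data()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(x) {
  bins <- if (inherits(x, "picnicc_performance")) {
    attr(x, "calibration")
  } else {
    as_tibble(x)
  }
  if (is.null(bins) || nrow(bins) == 0) {
    abort("No calibration bin data available.")
  }
  p <- ggplot(bins, aes(x = .data$mean_pred, y = .data$obs_prop)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    geom_point(aes(size = .data$n), alpha = 0.8) +
    geom_line(alpha = 0.5) +
    scale_size_area(max_size = 4, guide = "none") +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(
      x = "Mean predicted risk of MDI",
      y = "Observed proportion with MDI"
    ) +
    theme_minimal()
  if ("study_id" %in% names(bins) && length(unique(bins$study_id)) > 1) {
    p <- p + facet_wrap(~study_id)
  }
  p
}

#' Forest plot of a pooled metric
#'
#' Per-study estimates with 95% CIs, the random-effects pooled row, and
#' the 95% prediction interval when available.
#'
#' @param pooled A `picnicc_pooled` object.
#' @return A ggplot object.
#' @export
plot_forest <- function(pooled) {
  fd <- forest_data(pooled)
  fd$label <- factor(fd$label, levels = rev(fd$label))
  ref <- switch(pooled$metric,
    c_statistic = 0.5,
    e_o_ratio = 1,
    calib_slope = 1,
    NA_real_
  )
  p <- ggplot(fd, aes(x = .data$estimate, y = .data$label)) +
    geom_errorbarh(
      aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.2
    ) +
    geom_point(aes(shape = .data$row, size = .data$row)) +
    scale_shape_manual(
      values = c(study = 15, pooled = 18, prediction_interval = 5),
      guide = "none"
    ) +
    scale_size_manual(
      values = c(study = 2, pooled = 4, prediction_interval = 3),
      guide = "none"
    ) +
    labs(x = pooled$metric, y = NULL) +
    theme_minimal()
  if (is.finite(ref)) {
    p <- p + geom_vline(xintercept = ref, linetype = "dashed", alpha = 0.5)
  }
  p
}

#' ROC-space plot of a bivariate sensitivity/specificity summary
#'
#' Per-study crosshairs, the pooled summary point, and its confidence and
#' prediction ellipses, on 1 - specificity vs sensitivity axes (an ideal
#' rule sits in the top-left corner).
#'
#' @param biv A `picnicc_bivariate` object.
#' @return A ggplot object.
#' @export
plot_roc_space <- function(biv) {
  rd <- rocspace_data(biv)
  studies <- filter(rd, .data$part == "study")
  pooled <- filter(rd, .data$part == "pooled")
  conf <- filter(rd, .data$part == "ellipse_confidence")
  pred <- filter(rd, .data$part == "ellipse_prediction")
  ggplot(mapping = aes(x = 1 - .data$spec, y = .data$sens)) +
    geom_errorbar(
      data = studies,
      aes(ymin = .data$sens_lo, ymax = .data$sens_hi),
      width = 0, alpha = 0.6
    ) +
    geom_errorbarh(
      data = studies,
      aes(xmin = 1 - .data$spec_hi, xmax = 1 - .data$spec_lo),
      height = 0, alpha = 0.6
    ) +
    geom_point(data = studies, shape = 3, size = 2) +
    geom_path(data = conf, colour = "red", linewidth = 0.8) +
    geom_path(data = pred, colour = "red", linetype = "dashed") +
    geom_point(data = pooled, colour = "red", size = 3) +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "1 - specificity", y = "Sensitivity") +
    theme_minimal()
}

#' @export
autoplot.picnicc_performance <- function(object, ...) {
  plot_calibration(object)
}

#' @export
autoplot.picnicc_pooled <- function(object, ...) {
  plot_forest(object)
}

#' @export
autoplot.picnicc_bivariate <- function(object, ...) {
  plot_roc_space(object)
}
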