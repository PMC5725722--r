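#' Bland-Altman plot
#'
#' Per-item differences against per-item means, with the mean difference
#' (thick line) and the 95% limits of agreement at +/- 1.96 SD (dashed).
#'
#' @param object A [bland_altman()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meg_bland_altman
#' @export
autoplot.meg_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two approaches",
                  y = "Difference (template - native)") +
    ggplot2::theme_minimal()
}

#' Heatmap of global ICCs by band and measure
#'
#' @param object A [run_experiment()] report.
#' @param ... Unused.
#' @return A ggplot object faceted by displacement level and method.
#' @method autoplot meg_consistency_report
#' @export
autoplot.meg_consistency_report <- function(object, ...) {
  ggplot2::ggplot(object$global_icc,
                  ggplot2::aes(x = .data$band, y = .data$measure,
                               fill = .data$icc)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(method ~ displacement,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(NA, 1)) +
    ggplot2::labs(x = "Frequency band", y = "Global measure",
                  fill = "ICC(3,1)") +
    ggplot2::theme_minimal()
}

#' Representative-voxel distance versus power consistency
#'
#' Scatter of per-ROI representative-voxel distance against the per-ROI
#' relative-power ICC, faceted by band, with a linear trend. The expected
#' relationship under anatomical mismatch is negative: larger displacement,
#' lower consistency.
#'
#' @param report A [run_experiment()] report (or a tibble with columns
#'   `band`, `distance`, `icc`).
#' @return A ggplot object.
#' @export
plot_distance_icc <- function(report) {
  df <- if (inherits(report, "meg_consistency_report")) {
    report$distance_points
  } else {
    tibble::as_tibble(report)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$icc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick") +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = "Representative-voxel distance (mm)",
                  y = "Relative-power ICC(3,1)") +
    ggplot2::theme_minimal()
}
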