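# ggplot2 figures for study results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the cross-patient SUV difference histogram
#'
#' Mean per-bin voxel counts over patients with a +/- one standard error
#' ribbon, against the per-voxel percentage SUV difference.
#'
#' @param report a `study_report` (or a tibble from [histogram_summary()]).
#' @return a ggplot.
#' @export
plot_difference_histogram <- function(report) {
  h <- if (inherits(report, "study_report")) report$histogram else report
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$mean_count)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_count - .data$se_count,
                                      ymax = .data$mean_count + .data$se_count),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "per-voxel SUV difference, CTACstd vs CTACcba (%)",
                  y = "mean voxel count per bin") +
    ggplot2::theme_minimal()
}

#' Plot GTV volume differences against lesion SUVmean
#'
#' Reproduces the diagnostic view of the mechanism: fixed-threshold
#' (semi-manual) contours shrink more on the hardware-omitted image for less
#' FDG-avid lesions, while relative-threshold contours barely change.
#'
#' @param report a `study_report`.
#' @return a ggplot.
#' @export
plot_volume_differences <- function(report) {
  ggplot2::ggplot(report$contours,
                  ggplot2::aes(x = .data$suv_mean_cba,
                               y = .data$pct_volume_diff,
                               colour = .data$method,
                               shape = .data$lesion_label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "lesion SUVmean on CTACcba (g/mL)",
                  y = "GTV volume difference (%)",
                  colour = "contour method", shape = "lesion") +
    ggplot2::theme_minimal()
}

#' Autoplot a study report
#'
#' @param object a `study_report`.
#' @param type `"histogram"` or `"volumes"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.study_report <- function(object, type = c("histogram", "volumes"),
                                  ...) {
  switch(match.arg(type),
         histogram = plot_difference_histogram(object),
         volumes = plot_volume_differences(object))
}
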