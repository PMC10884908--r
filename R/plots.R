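#' Plot helpers
#'
#' ggplot2 visualisations for the main result types: sensor illuminance
#' profiles from the ray tracer, FOV sampling discrepancies, and coverage
#' sweeps.
#'
#' @param object,x object to plot.
#' @param ... unused.
#' @return A ggplot.
#' @name sheetscan-plots
NULL

#' @rdname sheetscan-plots
#' @export
autoplot.sensor_profile <- function(object, ...) {
  cfg <- attr(object, "config")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$bin_center_um,
                                    y = .data$illuminance)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "sensor position (um)", y = "illuminance (rays/bin)",
                  title = sprintf("sheet: %s", cfg$sheet))
  if (nrow(cfg$cells)) {
    p <- p + ggplot2::geom_vline(xintercept = cfg$cells$center_um,
                                 linetype = "dotted", colour = "red",
                                 alpha = 0.5)
  }
  p
}

#' @rdname sheetscan-plots
#' @export
autoplot.fov_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$k),
                               y = .data$discrepancy_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "fields of view sampled (k of 25)",
                  y = "discrepancy vs whole-vessel count (%)")
}

#' @rdname sheetscan-plots
#' @param sweep tibble from [coverage_sweep()].
#' @export
plot_coverage_sweep <- function(sweep, ...) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$hole_diameter_um,
                               y = 100 * .data$coverage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "hole diameter (um)",
                  y = "visualization-band coverage (%)")
}
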