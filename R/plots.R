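#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dose-response curve family
#'
#' Mean well intensity versus concentration (log axis), one line per
#' exposure, with +/- 1 SD ribbons.
#'
#' @param object A `response_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.response_curve <- function(object, ...) {
  d <- dplyr::mutate(object$data, exposure = factor(.data$exposure_ms))
  ggplot2::ggplot(d, ggplot2::aes(.data$concentration, .data$mean,
                                  color = .data$exposure,
                                  group = .data$exposure)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = .data$exposure),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (M)", y = "well intensity (counts)",
                  color = "exposure (ms)", fill = "exposure (ms)") +
    ggplot2::theme_minimal()
}

#' Plot a filter-series spectral response
#'
#' Signal versus long-pass cut-on wavelength, faceted by region, colored by
#' channel.
#'
#' @param object A `spectral_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$cuton_nm, .data$signal,
                               color = .data$channel)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_color_manual(values = c(R = "#c0392b", G = "#27ae60",
                                           B = "#2980b9", gray = "grey30")) +
    ggplot2::labs(x = "long-pass cut-on (nm)", y = "mean counts") +
    ggplot2::theme_minimal()
}

#' Plot a lane densitometry profile
#'
#' @param object A `lane_profile`.
#' @param bands Optional band table from [detect_bands()] to annotate.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lane_profile <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$distance_px, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from well (px)", y = "intensity (counts)") +
    ggplot2::theme_minimal()
  if (!is.null(bands) && nrow(bands) > 0)
    p <- p + ggplot2::geom_vline(xintercept = bands$position_px,
                                 linetype = "dotted", color = "#c0392b")
  p
}

#' Plot a growth track
#'
#' Segmented area versus time on a log scale, with the fitted exponential
#' trend.
#'
#' @param object A `growth_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_track <- function(object, ...) {
  d <- dplyr::filter(object$data, .data$segmented)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$area_px2)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#2980b9", linewidth = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "specimen area (px^2)") +
    ggplot2::theme_minimal()
}

#' Plate heat map of per-well percent deviation
#'
#' @param deviations Tibble from [percent_deviation()] carrying `row`,
#'   `col`, `deviation_pct` (e.g. built on [well_intensities()] output).
#' @return A ggplot.
#' @export
plot_plate_deviation <- function(deviations) {
  stopifnot(all(c("row", "col", "deviation_pct") %in% names(deviations)))
  ggplot2::ggplot(deviations,
                  ggplot2::aes(.data$col, .data$row,
                               fill = .data$deviation_pct)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_y_reverse(breaks = 1:8, labels = LETTERS[1:8]) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "% dev") +
    ggplot2::theme_minimal()
}
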