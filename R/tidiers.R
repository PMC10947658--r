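#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname led_linearity
#' @param x A `linearity_fit`.
#' @param ... Unused.
#' @export
tidy.linearity_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname led_linearity
#' @export
glance.linearity_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared,
                 worst_index = x$worst_index,
                 worst_residual = x$residuals$residual[x$worst_index],
                 n = nrow(x$residuals))
}

#' @rdname sensor_calibration
#' @param x A `sensor_fit`.
#' @param ... Unused.
#' @export
tidy.sensor_fit <- function(x, ...) {
  tibble::tibble(term = c("bottom", "top", "ec50_molar", "slope"),
                 estimate = c(x$bottom, x$top, x$ec50_molar, x$slope))
}

#' @rdname sensor_calibration
#' @export
glance.sensor_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, ec50_molar = x$ec50_molar,
                 n = nrow(x$data))
}

#' @rdname migration_fit
#' @param x A `migration_model`.
#' @param ... Unused.
#' @export
tidy.migration_model <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname migration_fit
#' @export
glance.migration_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared)
}

#' @rdname growth_track
#' @param x A `growth_track`.
#' @param ... Unused.
#' @export
tidy.growth_track <- function(x, ...) {
  tibble::tibble(term = "rate", estimate = x$rate,
                 conf_low = x$rate_ci[1], conf_high = x$rate_ci[2])
}

#' @rdname growth_track
#' @export
glance.growth_track <- function(x, ...) {
  tibble::tibble(rate = x$rate, model = x$model,
                 n_segmented = sum(x$data$segmented),
                 n_frames = nrow(x$data))
}
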