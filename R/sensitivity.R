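#' Build dose-response curves from an exposure sweep
#'
#' Groups replicate wells per concentration per exposure and computes mean,
#' SD and n of the per-well intensities. Wells mapped to concentration 0 are
#' the blanks; their statistics are kept separately per exposure (they feed
#' the detection-limit criterion).
#'
#' @param sweep An [image_stack()] whose frames carry acquisition settings
#'   with exposures.
#' @param grid A `well_grid` from [detect_grid()].
#' @param plate_map Data frame mapping `label` to `concentration` (molar);
#'   wells absent from the map are ignored.
#' @param channel Channel to quantify.
#' @param background Background mode for [well_intensities()]; annulus
#'   subtraction is the default for dilution plates.
#' @return An object of class `response_curve`: list with `data` (tibble
#'   `exposure_ms`, `concentration`, `mean`, `sd`, `n`), `blanks` (tibble
#'   `exposure_ms`, `blank_mean`, `blank_sd`, `blank_n`), `saturation`.
#' @export
build_curves <- function(sweep, grid, plate_map, channel = "G",
                         background = c("annulus", "none")) {
  background <- match.arg(background)
  plate_map <- tibble::as_tibble(plate_map)
  stopifnot(all(c("label", "concentration") %in% names(plate_map)))
  if (!any(plate_map$concentration == 0))
    stop("plate map has no blank wells (concentration 0)")
  per_frame <- purrr::map_dfr(sweep$frames, function(f) {
    if (is.null(f$setting)) stop("frame is missing its acquisition setting")
    wi <- well_intensities(f, grid, channel = channel, background = background)
    dplyr::mutate(dplyr::inner_join(wi, plate_map, by = "label"),
                  exposure_ms = f$setting$exposure_ms)
  })
  grouped <- dplyr::summarise(
    dplyr::group_by(per_frame, .data$exposure_ms, .data$concentration),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop")
  grouped$sd[grouped$n == 1] <- 0
  blanks <- dplyr::filter(grouped, .data$concentration == 0)
  structure(list(
    data = dplyr::arrange(dplyr::filter(grouped, .data$concentration > 0),
                          .data$exposure_ms, dplyr::desc(.data$concentration)),
    blanks = tibble::tibble(exposure_ms = blanks$exposure_ms,
                            blank_mean = blanks$mean, blank_sd = blanks$sd,
                            blank_n = blanks$n),
    saturation = frame_saturation(sweep$frames[[1]]),
    channel = channel),
    class = "response_curve")
}

#' Construct a response curve from summary data
#'
#' Escape hatch for curves not built from images (e.g. plate-reader
#' exports or hand-built test cases).
#'
#' @param data Tibble `exposure_ms`, `concentration`, `mean`, `sd`, `n`.
#' @param blanks Tibble `exposure_ms`, `blank_mean`, `blank_sd`, `blank_n`.
#' @param saturation Full-scale counts.
#' @return A `response_curve`.
#' @export
response_curve <- function(data, blanks, saturation = 255) {
  structure(list(data = tibble::as_tibble(data),
                 blanks = tibble::as_tibble(blanks),
                 saturation = saturation, channel = NA_character_),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %d exposure(s) x %d concentration(s)\n",
              length(unique(x$data$exposure_ms)),
              length(unique(x$data$concentration))))
  invisible(x)
}

#' Normalize a response curve
#'
#' `"max"` divides each exposure series by its maximum; `"minmax"` maps each
#' series to `[0, 1]` as `(v - min) / (max - min)`. SDs are scaled by the
#' same factor. Both modes leave the series maximum at exactly 1.
#'
#' @param curve A `response_curve`.
#' @param mode `"max"` or `"minmax"`.
#' @return A normalized `response_curve`.
#' @export
normalize_curve <- function(curve, mode = c("max", "minmax")) {
  mode <- match.arg(mode)
  d <- dplyr::group_by(curve$data, .data$exposure_ms)
  d <- dplyr::group_modify(d, function(g, key) {
    if (mode == "max") {
      scale <- max(g$mean)
      offset <- 0
    } else {
      scale <- max(g$mean) - min(g$mean)
      offset <- min(g$mean)
      if (scale == 0) stop("constant series cannot be min-max normalized")
    }
    dplyr::mutate(g, sd = .data$sd / scale,
                  mean = (.data$mean - offset) / scale)
  })
  out <- curve
  out$data <- dplyr::ungroup(d)
  out
}

curve_thresholds <- function(curve, k) {
  dplyr::mutate(curve$blanks,
                threshold = .data$blank_mean + k * .data$blank_sd)
}

#' Limit of detection from an exposure-sweep response curve
#'
#' Per exposure, the detection threshold is `blank mean + k * blank SD`; a
#' concentration is detected if its mean signal exceeds the threshold at
#' that exposure. The LOD is the smallest concentration detected at any
#' exposure, subject to monotone closure: every larger tested concentration
#' must also be detected at some exposure (isolated noise-triggered
#' detections below an undetected concentration do not count).
#'
#' @param curve A `response_curve` with blank statistics.
#' @param k Blank-SD multiplier of the detection criterion.
#' @return Object of class `lod_result`: list with `lod_molar` (`NA` when
#'   nothing is detectable), `exposure_ms` (shortest exposure detecting the
#'   LOD), `k`, `thresholds`, `detected` (per concentration).
#' @export
detection_limit <- function(curve, k = 3) {
  if (nrow(curve$blanks) == 0) stop("no blank statistics in curve")
  thr <- curve_thresholds(curve, k)
  d <- dplyr::left_join(curve$data, thr[, c("exposure_ms", "threshold")],
                        by = "exposure_ms")
  d$hit <- d$mean > d$threshold
  per_conc <- dplyr::summarise(dplyr::group_by(d, .data$concentration),
                               detected = any(.data$hit), .groups = "drop")
  per_conc <- dplyr::arrange(per_conc, dplyr::desc(.data$concentration))
  run <- cumprod(per_conc$detected) == 1   # monotone closure from the top
  if (!any(run)) {
    return(structure(list(lod_molar = NA_real_, exposure_ms = NA_real_,
                          k = k, thresholds = thr, detected = per_conc,
                          status = "none detectable"),
                     class = "lod_result"))
  }
  lod <- min(per_conc$concentration[run])
  hits <- dplyr::filter(d, .data$concentration == lod, .data$hit)
  structure(list(lod_molar = lod, exposure_ms = min(hits$exposure_ms),
                 k = k, thresholds = thr, detected = per_conc,
                 status = "ok"),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  if (is.na(x$lod_molar)) cat("<lod_result> none detectable\n")
  else cat(sprintf("<lod_result> LOD %.3g M at %g ms (blank + %g sd)\n",
                   x$lod_molar, x$exposure_ms, x$k))
  invisible(x)
}

#' Quantifiable dynamic range at one exposure
#'
#' The lowest quantifiable concentration is the smallest one above the
#' detection threshold at that exposure; the highest is the largest whose
#' mean stays below `sat_frac` of full scale. Range width is reported in
#' decades.
#'
#' @param curve A `response_curve`.
#' @param exposure_ms Exposure to evaluate (must be in the curve).
#' @param k Blank-SD multiplier.
#' @param sat_frac Saturation guard as a fraction of full scale.
#' @return List: `lowest`, `highest` (molar), `decades`, `empty`.
#' @export
dynamic_range <- function(curve, exposure_ms, k = 3, sat_frac = 0.9) {
  d <- dplyr::filter(curve$data, .data$exposure_ms == !!exposure_ms)
  if (nrow(d) == 0) stop("exposure not present in curve")
  thr <- curve_thresholds(curve, k)
  thr <- thr$threshold[thr$exposure_ms == exposure_ms]
  det <- d$concentration[d$mean > thr]
  unsat <- d$concentration[d$mean < sat_frac * curve$saturation]
  if (length(det) == 0 || length(unsat) == 0 || min(det) > max(unsat))
    return(list(lowest = NA_real_, highest = NA_real_, decades = 0,
                empty = TRUE))
  lo <- min(det); hi <- max(unsat)
  list(lowest = lo, highest = hi, decades = log10(hi / lo), empty = FALSE)
}

#' Recommend an exposure for a target concentration range
#'
#' Returns the exposure that keeps the largest number of target-range
#' concentrations both detected (above blank + k SD) and unsaturated (below
#' `sat_frac` of full scale); ties go to the shorter exposure.
#'
#' @param curve A `response_curve`.
#' @param target_range `c(c_lo, c_hi)` in molar.
#' @param k Blank-SD multiplier.
#' @param sat_frac Saturation guard.
#' @return Exposure in ms.
#' @export
recommend_exposure <- function(curve, target_range, k = 3, sat_frac = 0.9) {
  stopifnot(length(target_range) == 2)
  lo <- min(target_range); hi <- max(target_range)
  thr <- curve_thresholds(curve, k)
  d <- dplyr::left_join(curve$data, thr[, c("exposure_ms", "threshold")],
                        by = "exposure_ms")
  d <- dplyr::filter(d, .data$concentration >= lo, .data$concentration <= hi)
  if (nrow(d) == 0) stop("target range contains no tested concentration")
  d$ok <- d$mean > d$threshold & d$mean < sat_frac * curve$saturation
  sc <- dplyr::summarise(dplyr::group_by(d, .data$exposure_ms),
                         covered = sum(.data$ok), .groups = "drop")
  if (max(sc$covered) == 0) stop("no exposure covers any target concentration")
  best <- dplyr::filter(sc, .data$covered == max(sc$covered))
  min(best$exposure_ms)
}

#' Four-parameter logistic sensor calibration
#'
#' Fits `y = bottom + (top - bottom) / (1 + 10^(slope * (log10(EC50) - x)))`
#' to a (normalized) response versus `x = log10(concentration)` at one
#' exposure, via Levenberg-Marquardt least squares. Initialization: bottom
#' and top from the series min/max, EC50 from the mid-response crossing,
#' slope sign from the trend.
#'
#' @param curve A `response_curve` (normalize first if desired).
#' @param exposure_ms Exposure to fit; may be omitted when the curve holds a
#'   single exposure.
#' @return Object of class `sensor_fit`: `bottom`, `top`, `ec50_molar`,
#'   `slope`, `r_squared`, `fit` (the `nls` object), `data`.
#' @export
sensor_calibration <- function(curve, exposure_ms = NULL) {
  d <- curve$data
  if (is.null(exposure_ms)) {
    if (length(unique(d$exposure_ms)) != 1)
      stop("curve holds several exposures; pick one")
  } else {
    d <- dplyr::filter(d, .data$exposure_ms == !!exposure_ms)
    if (nrow(d) == 0) stop("exposure not present in curve")
  }
  d <- dplyr::filter(d, .data$concentration > 0)
  if (nrow(d) < 5) stop("need at least 5 concentrations spanning the transition")
  x <- log10(d$concentration); y <- d$mean
  if (max(y) - min(y) < 1e-9 * max(abs(y), 1))
    stop("flat response: no transition to fit")
  bottom0 <- min(y); top0 <- max(y)
  mid <- (bottom0 + top0) / 2
  ec0 <- x[which.min(abs(y - mid))]
  slope0 <- if (stats::cor(x, y) >= 0) 1 else -1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(slope * (lec50 - x))),
      start = list(bottom = bottom0, top = top0, lec50 = ec0, slope = slope0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("4PL fit did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(bottom = unname(co["bottom"]), top = unname(co["top"]),
                 ec50_molar = 10^unname(co["lec50"]),
                 slope = unname(co["slope"]), r_squared = r2, fit = fit,
                 data = tibble::tibble(log10_conc = x, response = y)),
            class = "sensor_fit")
}

#' @export
print.sensor_fit <- function(x, ...) {
  cat(sprintf(
    "<sensor_fit> bottom %.4g, top %.4g, EC50 %.3g M, slope %.3g, R^2 %.5f\n",
    x$bottom, x$top, x$ec50_molar, x$slope, x$r_squared))
  invisible(x)
}
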