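#' Black-level characterization from a dark-frame stack
#'
#' Pooled per-channel mean and standard deviation of a dark series, plus a
#' pass/fail flag: calibration is flagged as needed when any channel mean
#' exceeds `threshold` counts.
#'
#' @param dark An [image_stack()] of dark frames.
#' @param threshold Acceptable channel-mean offset (counts).
#' @return Tibble: `channel`, `mean`, `sd`, `n_pixels`,
#'   `calibration_needed`.
#' @export
black_level <- function(dark, threshold = 1.0) {
  st <- stack_mean_std(dark)
  st$calibration_needed <- st$mean > threshold
  st
}

srgb_to_lab <- function(rgb255) {
  grDevices::convertColor(rgb255 / 255, from = "sRGB", to = "Lab")
}

#' Color accuracy versus reference patch values
#'
#' CIE76 color difference after converting 8-bit sRGB to CIELAB (D65):
#' `deltaE = sqrt(dL^2 + da^2 + db^2)` per patch.
#'
#' @param measured,reference Data frames (or matrices) with `r`, `g`, `b`
#'   columns on the 0-255 scale, equal length.
#' @return Tibble with per-patch `delta_e`; attributes `mean_delta_e`,
#'   `max_delta_e`.
#' @export
color_accuracy <- function(measured, reference) {
  as_rgb <- function(x) {
    if (is.data.frame(x)) x <- as.matrix(x[, c("r", "g", "b")])
    matrix(as.numeric(x), ncol = 3)
  }
  m <- as_rgb(measured); r <- as_rgb(reference)
  if (nrow(m) != nrow(r)) stop("measured and reference lengths differ")
  de <- sqrt(rowSums((srgb_to_lab(m) - srgb_to_lab(r))^2))
  out <- tibble::tibble(patch = seq_len(nrow(m)), delta_e = de)
  attr(out, "mean_delta_e") <- mean(de)
  attr(out, "max_delta_e") <- max(de)
  out
}

#' Radial lens-distortion check on a dot-grid chart
#'
#' Detects grid dots (threshold at half range, connected components,
#' intensity-weighted centroids), assigns integer lattice indices from the
#' median nearest-neighbor pitch, and fits the radial model
#' `r' = r (1 + k1 r^2)` about the image center as
#' `r' = alpha rho + beta rho^3` over index radii `rho`
#' (`k1 = beta / alpha^3`). The principal point is assumed at the image
#' center.
#'
#' @param frame An [image_frame()] of a dot-grid chart.
#' @param tol `|k1|` below which the lens is classified distortion-free
#'   (1/px^2).
#' @param channel Detection channel.
#' @return List: `k1` (1/px^2), `classification` (`"none"`, `"barrel"`,
#'   `"pincushion"`), `n_points`, `pitch_px`.
#' @export
distortion_check <- function(frame, tol = 1e-8, channel = "gray") {
  m <- channel_matrix(frame, channel)
  # low threshold keeps most of each dot's Gaussian mass, so the
  # intensity-weighted centroids are good to well under 0.1 px
  thr <- min(m) + 0.05 * (max(m) - min(m))
  lab <- EBImage::bwlabel(m > thr)
  n <- max(lab)
  if (n < 9) stop("fewer than 9 grid crossings found")
  idx <- which(lab > 0, arr.ind = TRUE)
  wts <- m[idx]
  labs <- lab[idx]
  cy <- tapply(wts * (idx[, 1] - 1), labs, sum) / tapply(wts, labs, sum)
  cx <- tapply(wts * (idx[, 2] - 1), labs, sum) / tapply(wts, labs, sum)
  ctr <- (dim(m) - 1) / 2
  dy <- cy - ctr[1]; dx <- cx - ctr[2]
  # integer lattice indices from the median nearest-neighbor spacing
  pts <- cbind(dy, dx)
  dmat <- as.matrix(stats::dist(pts))
  diag(dmat) <- Inf
  pitch <- stats::median(apply(dmat, 1, min))
  i <- round(dy / pitch); j <- round(dx / pitch)
  rho <- sqrt(i^2 + j^2)
  rp <- sqrt(dy^2 + dx^2)
  keep <- rho > 0
  fit <- stats::lm(rp[keep] ~ 0 + rho[keep] + I(rho[keep]^3))
  alpha <- stats::coef(fit)[1]; beta <- stats::coef(fit)[2]
  k1 <- unname(beta / alpha^3)
  cls <- if (abs(k1) < tol) "none" else if (k1 < 0) "barrel" else "pincushion"
  list(k1 = k1, classification = cls, n_points = n, pitch_px = unname(alpha))
}

#' LED power linearity versus drive level
#'
#' Ordinary least squares `power = slope * drive + intercept`, with the
#' per-point residuals and the index of the worst offender. Zero-variance
#' power (degenerate input) is reported as slope 0 and R-squared 0 with a
#' warning.
#'
#' @param drive_levels Drive fractions (>= 3 distinct values).
#' @param powers Measured optical powers (same length).
#' @return Object of class `linearity_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `residuals` (tibble with `drive`, `power`, `fitted`,
#'   `residual`), `worst_index`.
#' @export
led_linearity <- function(drive_levels, powers) {
  if (length(drive_levels) < 3 || length(powers) != length(drive_levels))
    stop("need at least 3 (drive, power) points")
  if (length(unique(drive_levels)) < 3) stop("drive levels must be distinct")
  if (stats::var(powers) == 0) {
    warning("constant power response; R-squared undefined, reported as 0")
    res <- tibble::tibble(drive = drive_levels, power = powers,
                          fitted = powers, residual = 0)
    fit <- structure(list(slope = 0, intercept = powers[1], r_squared = 0,
                          residuals = res, worst_index = 1L),
                     class = "linearity_fit")
    return(fit)
  }
  fit <- stats::lm(powers ~ drive_levels)
  res <- tibble::tibble(drive = drive_levels, power = powers,
                        fitted = stats::fitted(fit),
                        residual = stats::residuals(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 # exact synthetic data legitimately fits perfectly
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 residuals = res,
                 worst_index = unname(which.max(abs(res$residual)))),
            class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf("<linearity_fit> slope %.4g, intercept %.4g, R^2 %.6f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

# finely sampled profile across the three bars of one element, and its
# Michelson contrast: max over the full span, min over the inter-bar core
element_contrast <- function(m, el, step = 0.25) {
  x <- seq(el$x0, el$x0 + 5 * el$bar_w_px, by = step)
  y <- el$y0 + el$bar_len_px / 2
  prof <- bilinear_at(m, rep(y, length(x)), x)
  core <- x >= el$x0 + el$bar_w_px & x <= el$x0 + 4 * el$bar_w_px
  imax <- max(prof); imin <- min(prof[core])
  if (imax + imin == 0) return(0)
  (imax - imin) / (imax + imin)
}

#' Finest resolvable element of a 1951 USAF target image
#'
#' Measures Michelson contrast `(Imax - Imin) / (Imax + Imin)` on a profile
#' across the three bars of each element, walking from the coarsest to the
#' finest and stopping at the first element whose contrast drops below the
#' threshold (a monotone resolution cut). Requires the rendered element
#' layout (targets are rendered, or registered, with known geometry).
#'
#' @param frame An [image_frame()] of the target.
#' @param elements Element layout tibble ([usaf_layout()]; a [usaf_scene()]
#'   carries one in `$elements`).
#' @param contrast_threshold Minimum contrast to call an element resolved.
#' @param channel Channel to analyze.
#' @return List: `freq_lp_mm` (finest resolvable frequency), `group`,
#'   `element`, `line_width_um`, and `contrasts` (tibble per element:
#'   `group`, `element`, `freq_lp_mm`, `contrast`, `resolved`).
#' @export
usaf_resolution <- function(frame, elements, contrast_threshold = 0.1,
                            channel = "gray") {
  m <- channel_matrix(frame, channel)
  el <- dplyr::arrange(elements, .data$freq_lp_mm)
  el$contrast <- vapply(seq_len(nrow(el)),
                        function(i) element_contrast(m, el[i, ]), numeric(1))
  el$resolved <- FALSE
  finest <- NULL
  for (i in seq_len(nrow(el))) {
    if (el$contrast[i] >= contrast_threshold) {
      el$resolved[i] <- TRUE
      finest <- el[i, ]
    } else break
  }
  if (is.null(finest)) stop("below coarsest group")
  list(freq_lp_mm = finest$freq_lp_mm, group = finest$group,
       element = finest$element,
       line_width_um = lp_per_mm_to_um(finest$freq_lp_mm),
       contrasts = el[, c("group", "element", "freq_lp_mm", "contrast",
                          "resolved")])
}

#' Convert a spatial frequency to a line width
#'
#' One line is half a line pair, so `width_um = 500 / freq_lp_mm`.
#'
#' @param freq_lp_mm Frequency in line pairs per mm (> 0).
#' @return Line width in micrometres.
#' @export
lp_per_mm_to_um <- function(freq_lp_mm) {
  if (any(freq_lp_mm <= 0)) stop("frequency must be > 0")
  500 / freq_lp_mm
}
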