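#' Segment the specimen in a frame
#'
#' Otsu global threshold on the gray channel, largest connected foreground
#' component, holes filled. Works whenever the specimen contrasts with the
#' background; a flat frame raises `"no specimen"`.
#'
#' @param frame An [image_frame()].
#' @return A [region_mask()] with attributes `area_px2`, `centroid`
#'   (`c(row, col)`, 0-based), `major_axis_px` (ellipse-equivalent major
#'   axis length).
#' @export
segment_specimen <- function(frame) {
  g <- to_gray(frame) / frame_saturation(frame)
  if (max(g) - min(g) < 1e-6) stop("no specimen")
  th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  fg <- g > th
  if (!any(fg)) stop("no specimen")
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  comp <- lab == biggest
  comp <- EBImage::fillHull(comp) > 0
  idx <- which(comp, arr.ind = TRUE)
  ctr <- colMeans(idx) - 1
  cov <- stats::cov(idx)
  major <- 4 * sqrt(max(eigen(cov, symmetric = TRUE,
                              only.values = TRUE)$values))
  structure(region_mask(comp, label = "specimen"),
            area_px2 = sum(comp), centroid = unname(ctr),
            major_axis_px = major)
}

#' Track specimen growth through a time-lapse stack
#'
#' Segments every frame, assembles the area series, and estimates the
#' exponential growth rate as the least-squares slope of `ln(area)` versus
#' time (a linear-area fit is available as `model = "linear"`, reporting
#' the relative slope `d(area)/dt / mean(area)`). Frames that fail
#' segmentation are flagged, excluded from the fit, and reported with a
#' warning.
#'
#' @param stack An [image_stack()] with `times` (e.g. days).
#' @param model `"exponential"` (default) or `"linear"`.
#' @return Object of class `growth_track`: `data` (tibble `time`,
#'   `area_px2`, `area_mm2`, `major_axis_px`, `segmented`), `rate` (per
#'   time unit), `rate_ci` (95%), `fit`.
#' @export
growth_track <- function(stack, model = c("exponential", "linear")) {
  model <- match.arg(model)
  if (is.null(stack$times)) stop("stack has no timestamps")
  if (length(stack$frames) < 2) stop("need at least 2 frames")
  if (is.unsorted(stack$times, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  rows <- purrr::imap_dfr(stack$frames, function(f, i) {
    seg <- tryCatch(segment_specimen(f), error = function(e) NULL)
    pp <- f$pixel_pitch_um
    if (is.null(seg)) {
      tibble::tibble(time = stack$times[i], area_px2 = NA_real_,
                     area_mm2 = NA_real_, major_axis_px = NA_real_,
                     segmented = FALSE)
    } else {
      a <- attr(seg, "area_px2")
      tibble::tibble(time = stack$times[i], area_px2 = a,
                     area_mm2 = if (is.null(pp)) NA_real_
                                else a * (pp / 1000)^2,
                     major_axis_px = attr(seg, "major_axis_px"),
                     segmented = TRUE)
    }
  })
  if (any(!rows$segmented))
    warning(sum(!rows$segmented), " frame(s) failed segmentation; excluded")
  ok <- rows[rows$segmented, ]
  if (nrow(ok) < 2) stop("fewer than 2 frames segmented")
  if (model == "exponential") {
    fit <- stats::lm(log(area_px2) ~ time, data = ok)
    rate <- unname(stats::coef(fit)[2])
  } else {
    fit <- stats::lm(area_px2 ~ time, data = ok)
    rate <- unname(stats::coef(fit)[2]) / mean(ok$area_px2)
  }
  ci <- tryCatch(suppressWarnings(unname(stats::confint(fit)[2, ])),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(data = rows, rate = rate, rate_ci = ci, fit = fit,
                 model = model),
            class = "growth_track")
}

#' @export
print.growth_track <- function(x, ...) {
  cat(sprintf("<growth_track> %d point(s), %s rate %.4g [%.4g, %.4g] per time unit\n",
              nrow(x$data), x$model, x$rate, x$rate_ci[1], x$rate_ci[2]))
  invisible(x)
}
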