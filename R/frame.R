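#' Acquisition setting
#'
#' The knobs of a single exposure: shutter time, LED excitation channel and
#' drive level, and the emission filter in front of the camera.
#'
#' @param exposure_ms Shutter time in milliseconds (> 0).
#' @param led_channel One of `"blue_460"`, `"green_520"`, `"red_630"`,
#'   `"external_uv"`, `"off"`.
#' @param drive_level Fractional LED power command in `[0, 1]`.
#' @param filter A [filter_model()] or `NULL` for no emission filter.
#' @return An object of class `acquisition_setting`.
#' @export
acquisition_setting <- function(exposure_ms = 10,
                                led_channel = c("blue_460", "green_520", "red_630",
                                                "external_uv", "off"),
                                drive_level = 1,
                                filter = NULL) {
  led_channel <- match.arg(led_channel)
  stopifnot(is.numeric(exposure_ms), length(exposure_ms) == 1)
  if (exposure_ms <= 0) stop("exposure_ms must be > 0")
  if (drive_level < 0 || drive_level > 1) stop("drive_level must be in [0, 1]")
  if (!is.null(filter) && !inherits(filter, "filter_model"))
    stop("filter must be a filter_model or NULL")
  structure(list(exposure_ms = exposure_ms, led_channel = led_channel,
                 drive_level = drive_level, filter = filter),
            class = "acquisition_setting")
}

#' Emission filter model
#'
#' Ideal step filters: a long-pass filter transmits every wavelength at or
#' above its cut-on; a band-pass transmits `center +/- halfwidth`.
#' Transmission is 0 or 1 per wavelength.
#'
#' @param kind `"longpass"` or `"bandpass"`.
#' @param cuton_nm Cut-on wavelength (long-pass).
#' @param center_nm,halfwidth_nm Band-pass window.
#' @return An object of class `filter_model`.
#' @export
filter_model <- function(kind = c("longpass", "bandpass"),
                         cuton_nm = NULL, center_nm = NULL, halfwidth_nm = NULL) {
  kind <- match.arg(kind)
  if (kind == "longpass") {
    if (is.null(cuton_nm)) stop("longpass filter needs cuton_nm")
  } else {
    if (is.null(center_nm) || is.null(halfwidth_nm) || halfwidth_nm <= 0)
      stop("bandpass filter needs center_nm and halfwidth_nm > 0")
  }
  structure(list(kind = kind, cuton_nm = cuton_nm,
                 center_nm = center_nm, halfwidth_nm = halfwidth_nm),
            class = "filter_model")
}

#' Filter transmission at given wavelengths
#'
#' @param filter A [filter_model()] or `NULL` (transmits everything).
#' @param lambda_nm Wavelengths in nm.
#' @return 0/1 transmission vector.
#' @export
filter_pass <- function(filter, lambda_nm) {
  if (is.null(filter)) return(rep(1, length(lambda_nm)))
  if (filter$kind == "longpass") {
    as.numeric(lambda_nm >= filter$cuton_nm)
  } else {
    as.numeric(abs(lambda_nm - filter$center_nm) <= filter$halfwidth_nm)
  }
}

#' Image frame
#'
#' A demosaiced RGB image in detector counts. Pixels are stored as floats;
#' quantization happens only when a file is written.
#'
#' @param pixels H x W x 3 numeric array (channels ordered R, G, B), or an
#'   H x W matrix which is replicated into three identical channels.
#' @param bit_depth Sensor bit depth; counts live in `[0, 2^bit_depth - 1]`.
#' @param setting Optional [acquisition_setting()].
#' @param pixel_pitch_um Optional sample-plane pixel pitch (micrometres per
#'   pixel), used to convert areas to physical units.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, bit_depth = 8, setting = NULL, pixel_pitch_um = NULL) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3)
  if (dim(pixels)[3] != 3) stop("pixels must have exactly 3 channels (R, G, B)")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) stop("empty image")
  sat <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > sat))
    stop("counts must lie in [0, 2^bit_depth - 1]")
  structure(list(pixels = pixels, bit_depth = bit_depth, setting = setting,
                 pixel_pitch_um = pixel_pitch_um),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_frame> %d x %d x 3, %d-bit", d[1], d[2], x$bit_depth))
  if (!is.null(x$setting))
    cat(sprintf(", %g ms, LED %s @ %g", x$setting$exposure_ms,
                x$setting$led_channel, x$setting$drive_level))
  cat("\n")
  invisible(x)
}

#' @export
dim.image_frame <- function(x) dim(x$pixels)

frame_saturation <- function(frame) 2^frame$bit_depth - 1

#' Image stack
#'
#' An ordered series of frames sharing geometry and bit depth, optionally
#' time-stamped for time-lapse work.
#'
#' @param frames List of [image_frame()]s.
#' @param times Optional numeric timestamps (e.g. days), one per frame.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, times = NULL) {
  stopifnot(is.list(frames))
  if (length(frames) == 0) stop("empty stack")
  d <- dim(frames[[1]]$pixels)
  bd <- frames[[1]]$bit_depth
  for (f in frames) {
    if (!inherits(f, "image_frame")) stop("all elements must be image_frame")
    if (!identical(dim(f$pixels), d) || f$bit_depth != bd)
      stop("all frames must share H, W and bit_depth")
  }
  if (!is.null(times) && length(times) != length(frames))
    stop("times must have one entry per frame")
  structure(list(frames = frames, times = times), class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]]$pixels)
  cat(sprintf("<image_stack> %d frame(s), %d x %d, %d-bit\n",
              length(x$frames), d[1], d[2], x$frames[[1]]$bit_depth))
  invisible(x)
}

#' Rectangular region of interest
#'
#' Axis-aligned box in 0-based, half-open row/column coordinates: rows
#' `[row0, row1)`, columns `[col0, col1)`. Pixel centers sit at integer
#' coordinates, so pixel `(0, 0)` is covered by `region_box(0, 1, 0, 1)`.
#'
#' @param row0,row1,col0,col1 Box bounds (0-based, half-open).
#' @param label Optional region label.
#' @return An object of class `region`.
#' @export
region_box <- function(row0, row1, col0, col1, label = "") {
  if (row1 <= row0 || col1 <= col0) stop("empty region")
  structure(list(type = "box", row0 = row0, row1 = row1, col0 = col0,
                 col1 = col1, label = label), class = "region")
}

#' Mask-defined region of interest
#'
#' @param mask Logical H x W matrix, `TRUE` inside the region.
#' @param label Optional region label.
#' @return An object of class `region`.
#' @export
region_mask <- function(mask, label = "") {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("empty region")
  structure(list(type = "mask", mask = mask, label = label), class = "region")
}

# row/col index matrix (1-based) of the pixels inside a region, checked
# against the frame bounds
region_index <- function(frame, region) {
  d <- dim(frame$pixels)
  if (region$type == "box") {
    r0 <- floor(region$row0); r1 <- ceiling(region$row1)
    c0 <- floor(region$col0); c1 <- ceiling(region$col1)
    if (r0 < 0 || c0 < 0 || r1 > d[1] || c1 > d[2])
      stop("region outside image bounds")
    rows <- seq.int(r0 + 1L, r1)
    cols <- seq.int(c0 + 1L, c1)
    as.matrix(expand.grid(row = rows, col = cols))
  } else {
    if (!identical(dim(region$mask), d[1:2]))
      stop("region mask does not match image size")
    which(region$mask, arr.ind = TRUE)
  }
}

# extract one channel of a frame as an H x W matrix; "gray" applies the
# frame's luma weights
channel_matrix <- function(frame, channel = c("R", "G", "B", "gray"),
                           gray_weights = c(0.299, 0.587, 0.114)) {
  channel <- match.arg(channel)
  p <- frame$pixels
  switch(channel,
         R = p[, , 1], G = p[, , 2], B = p[, , 3],
         gray = gray_weights[1] * p[, , 1] + gray_weights[2] * p[, , 2] +
           gray_weights[3] * p[, , 3])
}
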