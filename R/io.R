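# Image and manifest I/O: 8-bit PNG, 8/16-bit TIFF, JSON/YAML manifests
# mapping file names to acquisition settings.

#' Write a frame to PNG or TIFF
#'
#' Counts are scaled by the frame's full-scale value and quantized by the
#' writer; processing stays in float until this point.
#'
#' @param frame An [image_frame()].
#' @param path Output path; format chosen by extension (`.png` or
#'   `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  sat <- frame_saturation(frame)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (frame$bit_depth > 8)
      stop("PNG output supports 8-bit frames only")
    png::writePNG(frame$pixels / sat, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(frame$pixels / sat, path,
                    bits.per.sample = frame$bit_depth)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read a frame from PNG or TIFF
#'
#' @param path Image path (8-bit PNG, or 8/16-bit TIFF; single-channel
#'   images are replicated to RGB).
#' @param setting Optional [acquisition_setting()] to attach.
#' @param pixel_pitch_um Optional sample-plane pixel pitch.
#' @return An [image_frame()] in detector counts.
#' @export
read_frame <- function(path, setting = NULL, pixel_pitch_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    bd <- 8
    px <- px * (2^bd - 1)
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    bd <- attr(px, "bits.per.sample")
    if (is.null(bd)) bd <- 8
    px <- px * (2^bd - 1)
  } else stop("unsupported image format: ", ext)
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]  # drop alpha
  if (length(dim(px)) == 3 && dim(px)[3] == 1) px <- px[, , 1]
  image_frame(px, bit_depth = bd, setting = setting,
              pixel_pitch_um = pixel_pitch_um)
}

setting_to_record <- function(setting) {
  flt <- setting$filter
  list(exposure_ms = setting$exposure_ms, led = setting$led_channel,
       drive = setting$drive_level,
       filter_kind = if (is.null(flt)) "none" else flt$kind,
       filter_cuton_nm = if (!is.null(flt) && flt$kind == "longpass")
         flt$cuton_nm else NA,
       filter_center_nm = if (!is.null(flt) && flt$kind == "bandpass")
         flt$center_nm else NA,
       filter_halfwidth_nm = if (!is.null(flt) && flt$kind == "bandpass")
         flt$halfwidth_nm else NA)
}

record_to_setting <- function(rec) {
  flt <- switch(rec$filter_kind %||% "none",
                none = NULL,
                longpass = filter_model("longpass",
                                        cuton_nm = rec$filter_cuton_nm),
                bandpass = filter_model("bandpass",
                                        center_nm = rec$filter_center_nm,
                                        halfwidth_nm = rec$filter_halfwidth_nm),
                stop("unknown filter_kind: ", rec$filter_kind))
  acquisition_setting(rec$exposure_ms, rec$led %||% "off",
                      rec$drive %||% 1, flt)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write an acquisition manifest
#'
#' One record per frame: `file`, `exposure_ms`, `led`, `drive`,
#' `filter_kind`, `filter_cuton_nm` (long-pass) or
#' `filter_center_nm`/`filter_halfwidth_nm` (band-pass).
#'
#' @param stack An [image_stack()] whose frames carry settings.
#' @param files File names, one per frame.
#' @param path Manifest path (`.json` or `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(stack, files, path) {
  stopifnot(length(files) == length(stack$frames))
  recs <- purrr::imap(stack$frames, function(f, i) {
    if (is.null(f$setting)) stop("frame ", i, " has no acquisition setting")
    c(list(file = files[i]), setting_to_record(f$setting))
  })
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(recs, path)
  } else stop("unsupported manifest format: ", ext)
  invisible(path)
}

#' Read an acquisition manifest
#'
#' @param path Manifest path (`.json` or `.yaml`/`.yml`).
#' @return Tibble with `file` and the acquisition-setting fields.
#' @export
read_manifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext == "json") jsonlite::read_json(path)
          else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else stop("unsupported manifest format: ", ext)
  purrr::map_dfr(recs, function(r)
    tibble::tibble(file = r$file, exposure_ms = r$exposure_ms,
                   led = r$led %||% "off", drive = r$drive %||% 1,
                   filter_kind = r$filter_kind %||% "none",
                   filter_cuton_nm = r$filter_cuton_nm %||% NA_real_,
                   filter_center_nm = r$filter_center_nm %||% NA_real_,
                   filter_halfwidth_nm = r$filter_halfwidth_nm %||% NA_real_))
}

#' Save a stack as image files plus a manifest
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param format `"png"` or `"tiff"`.
#' @return The manifest path, invisibly.
#' @export
save_stack <- function(stack, dir, prefix = "frame", format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "png") "png" else "tif"
  files <- sprintf("%s_%03d.%s", prefix, seq_along(stack$frames), ext)
  for (i in seq_along(stack$frames))
    write_frame(stack$frames[[i]], file.path(dir, files[i]))
  write_manifest(stack, files, file.path(dir, paste0(prefix, "_manifest.json")))
}

#' Load a stack from a manifest
#'
#' @param manifest_path Manifest file written by [write_manifest()].
#' @param dir Directory holding the image files (defaults to the manifest's
#'   directory).
#' @param times Optional timestamps.
#' @return An [image_stack()] with per-frame settings attached.
#' @export
load_stack <- function(manifest_path, dir = dirname(manifest_path),
                       times = NULL) {
  man <- read_manifest(manifest_path)
  frames <- purrr::pmap(man, function(file, ...) {
    rec <- list(...)
    read_frame(file.path(dir, file), setting = record_to_setting(rec))
  })
  image_stack(frames, times = times)
}
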