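#' Supported long-pass cut-on wavelengths
#'
#' The eleven cut-on wavelengths of the instrument's long-pass filter set,
#' 435-695 nm.
#'
#' @return Numeric vector of cut-on wavelengths (nm).
#' @export
longpass_set <- function() c(435, 455, 475, 495, 515, 530, 550, 570, 610,
                             645, 695)

#' Build a filter-series spectral table
#'
#' Per-region, per-channel mean counts for every long-pass frame of a
#' filter sweep, ordered by cut-on wavelength. All frames must share
#' framing and carry a long-pass filter in their acquisition setting.
#'
#' @param stack An [image_stack()] of filter-series frames.
#' @param regions Named list of [region_box()]/[region_mask()]s (or a list
#'   whose elements carry labels).
#' @param channels Channels to extract (subset of `"R"`, `"G"`, `"B"`,
#'   `"gray"`).
#' @return A `spectral_series`: tibble `region`, `channel`, `cuton_nm`,
#'   `signal`.
#' @export
build_series <- function(stack, regions, channels = c("R", "G", "B")) {
  cutons <- vapply(stack$frames, function(f) {
    flt <- f$setting$filter
    if (is.null(flt) || flt$kind != "longpass")
      stop("every frame needs a long-pass filter in its setting")
    flt$cuton_nm
  }, numeric(1))
  if (anyDuplicated(cutons)) stop("duplicate filter cut-on in series")
  labels <- names(regions)
  if (is.null(labels))
    labels <- vapply(regions, function(r)
      if (nzchar(r$label)) r$label else stop("regions must be labelled"),
      character(1))
  rows <- purrr::imap_dfr(stack$frames, function(f, i) {
    purrr::map_dfr(seq_along(regions), function(ri) {
      purrr::map_dfr(channels, function(ch) {
        tibble::tibble(region = labels[ri], channel = ch,
                       cuton_nm = cutons[i],
                       signal = region_intensity(f, regions[[ri]], ch))
      })
    })
  })
  out <- dplyr::arrange(rows, .data$region, .data$channel, .data$cuton_nm)
  class(out) <- c("spectral_series", class(out))
  out
}

#' Signal versus cut-on wavelength for one channel
#'
#' A long-pass series must be nonincreasing in cut-on (each filter admits a
#' subset of the previous one); noise can violate this, so the series is
#' repaired by nonincreasing isotonic regression and adjusted points are
#' flagged. `channel = "gray"` combines R, G, B with Rec.601 luma weights
#' before repair.
#'
#' @param series A `spectral_series`.
#' @param channel `"R"`, `"G"`, `"B"` or `"gray"`.
#' @param region Region label; may be omitted when the series holds one
#'   region.
#' @param gray_weights Luma weights for `channel = "gray"`.
#' @return Tibble: `cuton_nm`, `signal` (repaired), `raw`, `adjusted`.
#' @export
channel_response <- function(series, channel = "gray", region = NULL,
                             gray_weights = c(0.299, 0.587, 0.114)) {
  if (nrow(series) == 0) stop("empty series")
  d <- tibble::as_tibble(series)
  if (is.null(region)) {
    if (length(unique(d$region)) != 1)
      stop("series holds several regions; pick one")
  } else d <- dplyr::filter(d, .data$region == !!region)
  if (channel == "gray") {
    wide <- tidyr::pivot_wider(d, id_cols = "cuton_nm",
                               names_from = "channel",
                               values_from = "signal")
    raw <- gray_weights[1] * wide$R + gray_weights[2] * wide$G +
      gray_weights[3] * wide$B
    cuton <- wide$cuton_nm
  } else {
    dd <- dplyr::filter(d, .data$channel == !!channel)
    raw <- dd$signal; cuton <- dd$cuton_nm
  }
  ord <- order(cuton)
  cuton <- cuton[ord]; raw <- raw[ord]
  # nonincreasing isotonic fit = negated nondecreasing fit
  rep_fit <- -stats::isoreg(seq_along(raw), -raw)$yf
  tibble::tibble(cuton_nm = cuton, signal = rep_fit, raw = raw,
                 adjusted = abs(rep_fit - raw) > 1e-9)
}

#' Differential band spectrum from a long-pass series
#'
#' Telescoping differences of a (monotone) long-pass response: band
#' `[lambda_i, lambda_{i+1})` carries energy `S(lambda_i) -
#' S(lambda_{i+1})`, and the terminal open band `[lambda_n, Inf)` carries
#' `S(lambda_n)`. Energies are floored at 0; their sum equals the
#' first-cut-on signal exactly for a monotone input.
#'
#' @param response Tibble from [channel_response()] (columns `cuton_nm`,
#'   `signal`, sorted).
#' @return A `band_spectrum` tibble: `lambda_lo`, `lambda_hi`, `energy`.
#' @export
band_reconstruct <- function(response) {
  if (nrow(response) < 2) stop("need at least 2 cut-ons")
  if (is.unsorted(response$cuton_nm, strictly = TRUE))
    stop("series must be sorted by cut-on")
  s <- response$signal
  n <- length(s)
  energy <- pmax(c(s[-n] - s[-1], s[n]), 0)
  out <- tibble::tibble(lambda_lo = response$cuton_nm,
                        lambda_hi = c(response$cuton_nm[-1], Inf),
                        energy = energy)
  class(out) <- c("band_spectrum", class(out))
  out
}

#' Anthocyanin excitation-ratio index
#'
#' Log fluorescence-excitation ratio of two registered frames acquired
#' through the same long-pass filter under red versus green excitation:
#' `AI = ln((F_red_exc + eps) / (F_green_exc + eps))` per pixel, with a
#' small `eps` guarding near-black pixels. Higher values track anthocyanin
#' accumulation (green-excited chlorophyll signal falls while red-excited
#' signal persists).
#'
#' @param f_green_exc,f_red_exc Registered [image_frame()]s (green / red
#'   excitation, same long-pass filter).
#' @param mask Optional logical matrix restricting the reported mean.
#' @param eps Stabilizer (counts).
#' @param channel Channel on which the ratio is computed.
#' @return List: `map` (H x W index matrix), `mean` (masked mean index).
#' @export
anthocyanin_index <- function(f_green_exc, f_red_exc, mask = NULL,
                              eps = 0.5, channel = "gray") {
  g <- channel_matrix(f_green_exc, channel)
  r <- channel_matrix(f_red_exc, channel)
  if (!identical(dim(g), dim(r))) stop("frames differ in shape")
  ai <- log((r + eps) / (g + eps))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ai), ncol(ai))
  if (!identical(dim(mask), dim(ai))) stop("mask shape mismatch")
  list(map = ai, mean = mean(ai[mask]))
}
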