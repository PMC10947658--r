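# Forward model: scene -> expected per-pixel signal -> camera counts.

#' Render a scene into an image frame
#'
#' The virtual instrument's forward model. Each pixel's expected signal is
#' `brightness * f_sat(c) * excitation(drive, channel) * filter_pass *
#' exposure_ms * illumination_field` (the factors that apply to the scene at
#' hand), and detector counts are
#' `clip(black_level + gain * signal + noise, 0, 2^bit_depth - 1)`.
#' Rendering is deterministic given `seed`; with all noise terms disabled it
#' is deterministic outright.
#'
#' @param scene A scene object ([plate_scene()], [gel_scene()],
#'   [usaf_scene()], [color_checker_scene()], [distortion_grid_scene()],
#'   [mineral_scene()], [specimen_scene()]).
#' @param setting An [acquisition_setting()].
#' @param camera A [camera_model()].
#' @param led An [led_model()].
#' @param seed Integer seed for the noise terms.
#' @return An [image_frame()].
#' @export
render <- function(scene, setting, camera = camera_model(),
                   led = led_model(), seed = 1L) {
  UseMethod("render")
}

#' @export
render.default <- function(scene, setting, camera = camera_model(),
                           led = led_model(), seed = 1L) {
  stop("unknown scene type")
}

# shared camera stage: expected pre-gain signal array -> counts
camera_apply <- function(signal, camera, seed) {
  s <- camera$gain * signal
  noisy <- camera$shot_noise || any(camera$read_noise_sd > 0)
  make <- function() {
    if (camera$shot_noise) s[] <- stats::rpois(length(s), s)
    counts <- s
    for (ch in 1:3) {
      counts[, , ch] <- counts[, , ch] + camera$black_level[ch]
      if (camera$read_noise_sd[ch] > 0)
        counts[, , ch] <- counts[, , ch] +
          stats::rnorm(length(counts[, , ch]), 0, camera$read_noise_sd[ch])
    }
    counts
  }
  counts <- if (noisy) withr::with_seed(seed, make()) else make()
  pmin(pmax(counts, 0), camera$saturation)
}

# expected per-channel rate (counts/ms pre-gain) of a fluorophore held at
# concentration c, under a setting, through the setting's filter
fluor_rate <- function(fluor, c_molar, setting, camera, led) {
  exc <- fluor$excitation[setting$led_channel]
  exc <- if (is.null(exc) || is.na(exc)) 0 else unname(exc)
  w_ch <- emission_channel_weight(fluor, setting$filter, camera)
  p <- led_power(led, setting)
  outer(fluor$k * c_molar * f_sat(c_molar, fluor$epsilon_l), w_ch) * exc * p
}

blank_signal <- function(dim) array(0, c(dim[1], dim[2], 3))

#' @export
render.plate_scene <- function(scene, setting, camera = camera_model(),
                               led = led_model(), seed = 1L) {
  lay <- scene$layout
  dim <- scene$dim
  field <- scene$illumination_field
  if (is.null(field)) {
    field <- if (scene$vignetting > 0) radial_vignette(dim, scene$vignetting)
             else matrix(1, dim[1], dim[2])
  }
  rates <- fluor_rate(scene$fluorophore, scene$concentrations, setting,
                      camera, led)                       # wells x 3
  centers <- plate_centers(lay)
  sig <- blank_signal(dim)
  xs <- seq_len(dim[2]) - 1; ys <- seq_len(dim[1]) - 1
  for (w in seq_len(nrow(centers))) {
    rr <- which(abs(ys - centers$center_row[w]) <= lay$radius_px)
    cc <- which(abs(xs - centers$center_col[w]) <= lay$radius_px)
    d2 <- outer((ys[rr] - centers$center_row[w])^2,
                (xs[cc] - centers$center_col[w])^2, `+`)
    disk <- d2 <= lay$radius_px^2
    for (ch in 1:3) {
      patch <- sig[rr, cc, ch]
      patch[disk] <- rates[w, ch]
      sig[rr, cc, ch] <- patch
    }
  }
  if (scene$background_rate > 0) sig <- sig + scene$background_rate
  t <- setting$exposure_ms
  for (ch in 1:3) sig[, , ch] <- sig[, , ch] * t * field
  frame_from(camera_apply(sig, camera, seed), camera, setting)
}

#' @export
render.gel_scene <- function(scene, setting, camera = camera_model(),
                             led = led_model(), seed = 1L) {
  dim <- scene$dim
  a <- scene$migration[1]; b <- scene$migration[2]
  w_ch <- emission_channel_weight(scene$fluorophore, setting$filter, camera)
  exc <- scene$fluorophore$excitation[setting$led_channel]
  exc <- if (is.null(exc) || is.na(exc)) 0 else unname(exc)
  p <- led_power(led, setting)
  ys <- seq_len(dim[1]) - 1
  lane_rate <- matrix(0, dim[1], length(scene$lanes))  # per-lane run profile
  for (l in seq_along(scene$lanes)) {
    lane <- scene$lanes[[l]]
    pos <- a - b * log10(lane$sizes)
    for (pp in pos)
      lane_rate[, l] <- lane_rate[, l] +
        exp(-(ys - pp)^2 / (2 * scene$band_sigma_px^2))
    lane_rate[, l] <- lane_rate[, l] * scene$fluorophore$k * lane$load
  }
  sig <- blank_signal(dim)
  for (l in seq_along(scene$lanes)) {
    x0 <- scene$margin_px + (l - 1) * (scene$lane_width_px + scene$lane_gap_px)
    cols <- seq.int(x0 + 1, x0 + scene$lane_width_px)
    for (ch in 1:3)
      sig[, cols, ch] <- sig[, cols, ch] + lane_rate[, l] * w_ch[ch]
  }
  sig <- sig * exc * p * setting$exposure_ms
  frame_from(camera_apply(sig, camera, seed), camera, setting)
}

# fractional pixel coverage of the three-bar pattern along x:
# bars occupy [x0 + 2iw, x0 + (2i+1)w), i = 0..2
bar_coverage <- function(px_centers, x0, w) {
  cdf <- function(x) {
    tot <- numeric(length(x))
    for (i in 0:2) {
      lo <- x0 + 2 * i * w; hi <- lo + w
      tot <- tot + pmin(pmax(x - lo, 0), hi - lo)
    }
    tot
  }
  cdf(px_centers + 0.5) - cdf(px_centers - 0.5)
}

interval_coverage <- function(px_centers, lo, hi) {
  pmin(px_centers + 0.5, hi) - pmax(px_centers - 0.5, lo)
}

#' @export
render.usaf_scene <- function(scene, setting, camera = camera_model(),
                              led = led_model(), seed = 1L) {
  dim <- scene$dim
  pattern <- matrix(0, dim[1], dim[2])
  xs <- seq_len(dim[2]) - 1; ys <- seq_len(dim[1]) - 1
  for (i in seq_len(nrow(scene$elements))) {
    e <- scene$elements[i, ]
    colcov <- bar_coverage(xs, e$x0, e$bar_w_px)
    rowcov <- pmax(interval_coverage(ys, e$y0, e$y0 + e$bar_len_px), 0)
    jj <- which(colcov > 0); ii <- which(rowcov > 0)
    pattern[ii, jj] <- pattern[ii, jj] + outer(rowcov[ii], colcov[jj])
  }
  sigma_px <- scene$blur_sigma_um * scene$scale_px_per_mm / 1000
  if (sigma_px > 0) pattern <- EBImage::gblur(pattern, sigma = sigma_px)
  sig <- array(scene$rate * setting$exposure_ms * pattern, c(dim, 3))
  frame_from(camera_apply(sig, camera, seed), camera, setting)
}

#' @export
render.color_checker_scene <- function(scene, setting, camera = camera_model(),
                                       led = led_model(), seed = 1L) {
  dim <- scene$dim
  sig <- blank_signal(dim)
  rgb <- as.matrix(scene$patches[, c("r", "g", "b")])
  for (i in seq_len(nrow(scene$patches))) {
    p <- scene$patches[i, ]
    rows <- seq.int(p$y0 + 1, p$y0 + scene$patch_px)
    cols <- seq.int(p$x0 + 1, p$x0 + scene$patch_px)
    for (ch in 1:3)
      sig[rows, cols, ch] <- rgb[i, ch] * scene$rate_scale
  }
  sig <- sig * setting$exposure_ms
  frame_from(camera_apply(sig, camera, seed), camera, setting)
}

#' @export
render.distortion_grid_scene <- function(scene, setting,
                                         camera = camera_model(),
                                         led = led_model(), seed = 1L) {
  dim <- scene$dim
  cy <- (dim[1] - 1) / 2; cx <- (dim[2] - 1) / 2
  m <- (scene$n_dots - 1) / 2
  pattern <- matrix(0, dim[1], dim[2])
  half <- ceiling(5 * scene$dot_sigma_px)
  for (i in -m:m) for (j in -m:m) {
    y <- i * scene$pitch_px; x <- j * scene$pitch_px
    r <- sqrt(y^2 + x^2)
    s <- 1 + scene$k1 * r^2
    yd <- cy + y * s; xd <- cx + x * s
    rr <- max(1, floor(yd) - half):min(dim[1], ceiling(yd) + half)
    cc <- max(1, floor(xd) - half):min(dim[2], ceiling(xd) + half)
    d2 <- outer(((rr - 1) - yd)^2, ((cc - 1) - xd)^2, `+`)
    pattern[rr, cc] <- pattern[rr, cc] + exp(-d2 / (2 * scene$dot_sigma_px^2))
  }
  sig <- array(scene$rate * setting$exposure_ms * pattern, c(dim, 3))
  frame_from(camera_apply(sig, camera, seed), camera, setting)
}

#' @export
render.mineral_scene <- function(scene, setting, camera = camera_model(),
                                 led = led_model(), seed = 1L) {
  dim <- scene$dim
  sig <- blank_signal(dim)
  p <- led_power(led, setting)
  for (reg in scene$regions) {
    em <- as.data.frame(reg$emission)
    w <- em$weight / sum(em$weight) * filter_pass(setting$filter, em$lambda_nm)
    qe <- camera$channel_response(em$lambda_nm)
    if (is.null(dim(qe))) qe <- matrix(qe, nrow = 3)
    w_ch <- as.numeric(qe %*% w)
    rows <- seq.int(reg$row0 + 1, reg$row1)
    cols <- seq.int(reg$col0 + 1, reg$col1)
    for (ch in 1:3)
      sig[rows, cols, ch] <- sig[rows, cols, ch] + reg$rate * w_ch[ch]
  }
  sig <- sig * p * setting$exposure_ms
  frame_from(camera_apply(sig, camera, seed), camera, setting)
}

#' @export
render.specimen_scene <- function(scene, setting, camera = camera_model(),
                                  led = led_model(), seed = 1L) {
  dim <- scene$dim
  th <- scene$angle_deg * pi / 180
  ys <- seq_len(dim[1]) - 1 - scene$center[1]
  xs <- seq_len(dim[2]) - 1 - scene$center[2]
  Y <- matrix(ys, dim[1], dim[2])
  X <- matrix(xs, dim[1], dim[2], byrow = TRUE)
  u <- cos(th) * X + sin(th) * Y
  v <- -sin(th) * X + cos(th) * Y
  inside <- (u / scene$a_px)^2 + (v / scene$b_px)^2 <= 1
  rate <- scene$bg_rate + (scene$fg_rate - scene$bg_rate) * inside
  sig <- array(rate * setting$exposure_ms, c(dim, 3))
  frame_from(camera_apply(sig, camera, seed), camera, setting)
}

frame_from <- function(counts, camera, setting) {
  image_frame(counts, bit_depth = camera$bit_depth, setting = setting)
}

#' Render a sweep of acquisition settings
#'
#' One frame per setting; the per-frame noise seed is `seed + index`
#' (1-based index), so a sweep is reproducible as a whole.
#'
#' @param scene A scene object.
#' @param settings List of [acquisition_setting()]s.
#' @param camera A [camera_model()].
#' @param led An [led_model()].
#' @param seed Base integer seed.
#' @return An [image_stack()].
#' @export
render_sweep <- function(scene, settings, camera = camera_model(),
                         led = led_model(), seed = 1L) {
  if (length(settings) == 0) stop("settings must be nonempty")
  frames <- purrr::imap(settings, function(s, i)
    render(scene, s, camera, led, seed = seed + i))
  image_stack(frames)
}

#' Simulate a dark-frame series
#'
#' Frames containing only per-channel black level plus Gaussian read noise,
#' clipped to `[0, saturation]` — the zero-clipped Gaussian model used for
#' black-level characterization.
#'
#' @param camera A [camera_model()].
#' @param n_frames Number of frames (>= 1).
#' @param H,W Frame size.
#' @param seed Integer seed.
#' @return An [image_stack()].
#' @export
dark_stack <- function(camera, n_frames, H, W, seed = 1L) {
  stopifnot(n_frames >= 1)
  frames <- withr::with_seed(seed, lapply(seq_len(n_frames), function(i) {
    px <- array(0, c(H, W, 3))
    for (ch in 1:3)
      px[, , ch] <- camera$black_level[ch] +
        if (camera$read_noise_sd[ch] > 0)
          stats::rnorm(H * W, 0, camera$read_noise_sd[ch]) else 0
    image_frame(pmin(pmax(px, 0), camera$saturation),
                bit_depth = camera$bit_depth)
  }))
  image_stack(frames)
}
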