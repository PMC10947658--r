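# Ready-made study configurations for the virtual instrument. Each preset
# bundles scene + settings + camera (+ plate map where relevant) so the
# characterization procedures can run end to end on one call.

#' Camera preset matching published dark-frame statistics
#'
#' Per-channel underlying `(mu, sigma)` are obtained by inverting the
#' zero-clipped Gaussian moment equations for the published dark-frame
#' means `[0.50, 0.36, 0.57]` and SDs `[0.84, 0.68, 0.87]` counts (R, G,
#' B), so a rendered dark stack reproduces those statistics.
#'
#' @param means,sds Target dark-frame per-channel mean and SD (counts).
#' @return A [camera_model()].
#' @export
preset_dark_camera <- function(means = c(0.50, 0.36, 0.57),
                               sds = c(0.84, 0.68, 0.87)) {
  par <- vapply(1:3, function(ch)
    match_clipped_normal(means[ch], sds[ch]), numeric(2))
  camera_model(bit_depth = 8, black_level = par[1, ],
               read_noise_sd = par[2, ])
}

#' FITC dilution-series sweep preset
#'
#' A 96-well plate holding a ten-step decade dilution of a FITC-like
#' fluorophore from `10^-3` to `10^-12` M in columns 1-10, triplicate rows
#' A-C, with row D as blanks; imaged under blue (460 nm) excitation through
#' a 542 +/- 25 nm band-pass at exposures 1, 10, 100, 1000, 2000 and
#' 10000 ms. Camera: 8-bit, read noise 0.5 counts, shot noise on.
#'
#' @param k Brightness constant (counts / M / ms) of the fluorophore.
#' @param exposures_ms Exposure sweep.
#' @param read_noise_sd Per-channel read noise (counts).
#' @return List: `scene`, `settings`, `camera`, `led`, `plate_map`,
#'   `layout`, `concentrations` (the decade series).
#' @export
preset_fitc_dilution <- function(k = 1e10,
                                 exposures_ms = c(1, 10, 100, 1000, 2000, 10000),
                                 read_noise_sd = 0.5) {
  layout <- plate_layout()
  conc_steps <- 10^-(3:12)
  conc <- matrix(0, layout$n_rows, layout$n_cols)
  conc[1:3, 1:10] <- matrix(conc_steps, 3, 10, byrow = TRUE)
  centers <- plate_centers(layout)
  pm_dil <- tibble::tibble(
    label = well_label(rep(1:3, each = 10), rep(1:10, 3)),
    concentration = rep(conc_steps, 3))
  pm_blank <- tibble::tibble(label = well_label(4, 1:12), concentration = 0)
  flt <- filter_model("bandpass", center_nm = 542, halfwidth_nm = 25)
  settings <- lapply(exposures_ms, function(t)
    acquisition_setting(t, "blue_460", 1, flt))
  camera <- camera_model(bit_depth = 8, black_level = c(0.50, 0.36, 0.57),
                         read_noise_sd = rep(read_noise_sd, 3),
                         shot_noise = TRUE)
  scene <- plate_scene(layout, conc, fluor_fitc(k = k))
  list(scene = scene, settings = settings, camera = camera,
       led = led_model(), plate_map = rbind(pm_dil, pm_blank),
       layout = layout, concentrations = conc_steps)
}

#' Uniform-concentration flatness-plate preset
#'
#' Every well at the same concentration (10 uM FITC), a radial vignetting
#' field, and noise scaled to a target per-well signal-to-noise ratio. The
#' brightness constant is chosen to put well means mid-scale (~150 counts)
#' at the 10 ms flatness exposure; read noise is set so that shot plus read
#' noise on the well mean hits the requested SNR.
#'
#' @param vignetting Radial vignetting amplitude (fraction at the corner).
#' @param snr Target per-well-mean signal-to-noise ratio.
#' @param concentration Well concentration (M).
#' @param exposure_ms Flatness exposure.
#' @param target_counts Desired well mean at the center (counts).
#' @return List: `scene`, `setting`, `camera`, `led`, `layout`.
#' @export
preset_flatness_plate <- function(vignetting = 0.02, snr = 200,
                                  concentration = 1e-5, exposure_ms = 10,
                                  target_counts = 150) {
  layout <- plate_layout()
  flt <- filter_model("bandpass", center_nm = 542, halfwidth_nm = 25)
  setting <- acquisition_setting(exposure_ms, "blue_460", 1, flt)
  camera0 <- camera_model()
  fl0 <- fluor_fitc(k = 1)
  per_unit_k <- fluor_rate(fl0, concentration, setting, camera0,
                           led_model())[1, 2] * exposure_ms
  k <- target_counts / per_unit_k
  # per-well-mean noise budget: shot variance S/n plus read variance
  n_pix <- sum(outer(seq(-12, 12), seq(-12, 12),
                     function(a, b) a^2 + b^2) <= (0.8 * layout$radius_px)^2)
  target_var <- (target_counts / snr)^2
  shot_var <- target_counts / n_pix
  read_sd_px <- sqrt(max(target_var - shot_var, 0) * n_pix)
  camera <- camera_model(bit_depth = 8, black_level = c(0.50, 0.36, 0.57),
                         read_noise_sd = rep(read_sd_px, 3),
                         shot_noise = TRUE)
  scene <- plate_scene(layout, concentration, fluor_fitc(k = k),
                       vignetting = vignetting)
  list(scene = scene, setting = setting, camera = camera,
       led = led_model(), layout = layout)
}

#' USAF resolution-target preset
#'
#' Groups 0-3 rendered at 100 px/mm with a 30 um Gaussian optical blur,
#' noise-free camera — the configuration used to score the instrument's
#' optical resolution.
#'
#' @param blur_sigma_um Optical blur SD (um).
#' @param scale_px_per_mm Sample-plane sampling.
#' @return List: `scene`, `setting`, `camera`, `led`.
#' @export
preset_usaf_target <- function(blur_sigma_um = 30, scale_px_per_mm = 100) {
  scene <- usaf_scene(groups = 0:3, scale_px_per_mm = scale_px_per_mm,
                      blur_sigma_um = blur_sigma_um, rate = 20)
  list(scene = scene,
       setting = acquisition_setting(10, "off", 0),
       camera = camera_model(), led = led_model())
}

#' 1 kb ladder sizes (bp)
#'
#' The fourteen fragment sizes of a standard 1 kb DNA ladder.
#'
#' @return Numeric vector of fragment sizes in bp.
#' @export
ladder_1kb <- function() c(250, 500, 750, 1000, 1500, 2000, 2500, 3000,
                           3500, 4000, 5000, 6000, 8000, 10000)

#' Agarose-gel ladder preset
#'
#' Four lanes of the 1 kb ladder at loads 10, 10, 20 and 20 mass units,
#' semilog migration `position = 1060 - 250 log10(bp)` px, band SD 4 px;
#' imaged on a 16-bit camera (headroom for the double-load lanes) under
#' blue excitation through a 515 nm long-pass.
#'
#' @param loads Lane loads (mass units).
#' @param band_sigma_px Band SD (px).
#' @return List: `scene`, `setting`, `camera`, `led`, `lane_boxes`
#'   (list of [region_box()] per lane), `sizes`.
#' @export
preset_gel_ladder <- function(loads = c(10, 10, 20, 20), band_sigma_px = 4) {
  sizes <- ladder_1kb()
  lanes <- lapply(loads, function(l) list(load = l, sizes = sizes))
  scene <- gel_scene(lanes, band_sigma_px = band_sigma_px,
                     fluorophore = fluor_gel_stain(k = 0.18))
  boxes <- lapply(seq_along(loads), function(l) {
    x0 <- scene$margin_px + (l - 1) * (scene$lane_width_px + scene$lane_gap_px)
    region_box(0, scene$dim[1], x0, x0 + scene$lane_width_px,
               label = paste0("lane", l))
  })
  list(scene = scene,
       setting = acquisition_setting(100, "blue_460", 1,
                                     filter_model("longpass", cuton_nm = 515)),
       camera = camera_model(bit_depth = 16),
       led = led_model(), lane_boxes = boxes, sizes = sizes)
}

#' Mineral filter-series preset
#'
#' Nine emitting regions in a 3 x 3 arrangement with emission lines spread
#' across 445-700 nm (two of them multi-line), imaged under UV excitation
#' through each of the eleven long-pass filters.
#'
#' @param exposure_ms Exposure per filter frame.
#' @return List: `scene`, `settings` (one per long-pass cut-on), `camera`,
#'   `led`, `regions` (named list of [region_box()]s).
#' @export
preset_minerals <- function(exposure_ms = 10) {
  lines <- list(445, 480, 515, 550, 585, 620, 660, 700,
                c(470, 610))                       # ninth: two-line emitter
  rates <- c(14, 16, 15, 18, 15, 16, 14, 15, 16)
  regions <- list(); scene_regions <- list()
  for (i in 1:9) {
    r <- (i - 1) %/% 3; cc <- (i - 1) %% 3
    row0 <- 20 + r * 75; col0 <- 25 + cc * 115
    lab <- paste0("mineral", i)
    em <- data.frame(lambda_nm = lines[[i]],
                     weight = rep(1 / length(lines[[i]]),
                                  length(lines[[i]])))
    scene_regions[[i]] <- list(label = lab, row0 = row0, row1 = row0 + 55,
                               col0 = col0, col1 = col0 + 90,
                               emission = em, rate = rates[i])
    regions[[lab]] <- region_box(row0, row0 + 55, col0, col0 + 90, lab)
  }
  scene <- mineral_scene(scene_regions)
  settings <- lapply(longpass_set(), function(con)
    acquisition_setting(exposure_ms, "external_uv", 1,
                        filter_model("longpass", cuton_nm = con)))
  list(scene = scene, settings = settings, camera = camera_model(),
       led = led_model(), regions = regions)
}

#' Growing-specimen time-lapse preset
#'
#' A ten-day series of a bright elliptical specimen on a dark background
#' whose area grows exponentially (default rate 0.35 per day, about a
#' 23-fold area increase over ten days, in line with a fast-growing larva).
#'
#' @param days Acquisition days.
#' @param rate_per_day Exponential area growth rate.
#' @param a0_px,b0_px Day-0 semi-axes (px).
#' @return List: `scenes` (one per day), `setting`, `camera`, `led`,
#'   `days`.
#' @export
preset_specimen_growth <- function(days = 0:9, rate_per_day = 0.35,
                                   a0_px = 12, b0_px = 6) {
  scenes <- lapply(days, function(d) {
    s <- exp(rate_per_day * d / 2)
    specimen_scene(a_px = a0_px * s, b_px = b0_px * s, angle_deg = 20)
  })
  list(scenes = scenes, setting = acquisition_setting(10, "off", 0),
       camera = camera_model(), led = led_model(), days = days)
}

#' Render a preset time-lapse into a stack
#'
#' @param preset Output of [preset_specimen_growth()].
#' @param seed Base seed (per-frame seeds derived as `seed + index`).
#' @return An [image_stack()] with timestamps.
#' @export
render_timelapse <- function(preset, seed = 1L) {
  frames <- purrr::imap(preset$scenes, function(s, i)
    render(s, preset$setting, preset$camera, preset$led, seed = seed + i))
  image_stack(frames, times = preset$days)
}
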