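# Scene descriptions consumed by render(). Each scene knows its canvas size
# and how to turn itself into a per-pixel, per-channel expected signal rate;
# the camera stage (black level, gain, noise, clipping) is shared.

#' Well-plate scene
#'
#' A microplate whose wells hold a fluorophore at per-well concentrations,
#' seen through an optional spatial illumination field (vignetting).
#'
#' @param layout A [plate_layout()].
#' @param concentrations Numeric vector (length `n_rows * n_cols`, row-major
#'   A1..H12) or matrix of molar concentrations; a single value is recycled.
#' @param fluorophore A [fluorophore_model()].
#' @param vignetting Radial vignetting amplitude `a`: the illumination field
#'   falls off as `1 - a * (r / r_corner)^2` about the image center. Ignored
#'   when `illumination_field` is supplied.
#' @param illumination_field Optional explicit H x W multiplier field.
#' @param background_rate Signal rate outside the wells (counts/ms).
#' @return An object of class `plate_scene`.
#' @export
plate_scene <- function(layout, concentrations, fluorophore,
                        vignetting = 0, illumination_field = NULL,
                        background_rate = 0) {
  n_wells <- layout$n_rows * layout$n_cols
  conc <- as.numeric(t(concentrations))
  if (length(conc) == 1) conc <- rep(conc, n_wells)
  if (length(conc) != n_wells)
    stop("need one concentration per well (row-major)")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  structure(list(layout = layout, concentrations = conc,
                 fluorophore = fluorophore, vignetting = vignetting,
                 illumination_field = illumination_field,
                 background_rate = background_rate,
                 dim = layout$image_dim),
            class = c("plate_scene", "scene"))
}

#' Agarose-gel scene
#'
#' Lanes of Gaussian bands placed by a semilog migration model
#' `position_px = a - b * log10(size_bp)` (distance from the well row;
#' `b > 0`, so smaller fragments travel farther). Band amplitude is
#' proportional to lane load.
#'
#' @param lanes List of `list(load = <mass units>, sizes = <bp vector>)`.
#' @param migration `c(a, b)` of the semilog migration model (px, px/decade).
#' @param band_sigma_px Gaussian band SD along the run direction (px).
#' @param fluorophore A [fluorophore_model()] for the stain; its `k` is
#'   interpreted as counts/ms per unit load at band center.
#' @param lane_width_px,lane_gap_px,margin_px Geometry.
#' @param height_px Image height (run direction).
#' @return An object of class `gel_scene`.
#' @export
gel_scene <- function(lanes, migration = c(a = 1060, b = 250),
                      band_sigma_px = 4,
                      fluorophore = fluor_gel_stain(),
                      lane_width_px = 40, lane_gap_px = 24, margin_px = 30,
                      height_px = 520) {
  if (migration[2] <= 0) stop("migration slope b must be > 0")
  W <- margin_px * 2 + length(lanes) * lane_width_px +
    (length(lanes) - 1) * lane_gap_px
  structure(list(lanes = lanes, migration = unname(migration),
                 band_sigma_px = band_sigma_px, fluorophore = fluorophore,
                 lane_width_px = lane_width_px, lane_gap_px = lane_gap_px,
                 margin_px = margin_px, dim = c(height_px, W)),
            class = c("gel_scene", "scene"))
}

#' Gel stain fluorophore preset
#'
#' Green-emitting intercalating-dye stand-in (blue-excited, 520 nm line).
#' `k` is counts/ms per unit lane load at band center.
#'
#' @param k Brightness (counts/ms per unit load).
#' @return A [fluorophore_model()].
#' @export
fluor_gel_stain <- function(k = 18) {
  fluorophore_model("gel stain", c(blue_460 = 1),
                    data.frame(lambda_nm = 520, weight = 1), k = k)
}

#' 1951 USAF three-bar target scene
#'
#' Vertical three-bar elements for the requested groups (six elements per
#' group, spatial frequency `2^(group + (element - 1) / 6)` lp/mm), rendered
#' with subpixel bar coverage and an optional Gaussian optical blur.
#'
#' @param groups Integer vector of group numbers.
#' @param scale_px_per_mm Pixels per millimetre at the sample plane.
#' @param blur_sigma_um Gaussian blur SD in micrometres (0 = none).
#' @param rate Bright-bar signal rate (counts/ms at the camera input).
#' @return An object of class `usaf_scene`; `$elements` holds the element
#'   layout used by [usaf_resolution()].
#' @export
usaf_scene <- function(groups = 0:3, scale_px_per_mm = 100,
                       blur_sigma_um = 0, rate = 20) {
  el <- usaf_layout(groups, scale_px_per_mm)
  H <- max(el$y0 + el$bar_len_px) + attr(el, "margin")
  W <- max(el$x0 + 5 * el$bar_w_px) + attr(el, "margin")
  structure(list(elements = el, scale_px_per_mm = scale_px_per_mm,
                 blur_sigma_um = blur_sigma_um, rate = rate,
                 dim = c(ceiling(H), ceiling(W))),
            class = c("usaf_scene", "scene"))
}

#' Element layout of a 1951 USAF target
#'
#' @param groups Integer group numbers.
#' @param scale_px_per_mm Pixels per millimetre.
#' @return Tibble with one row per element: `group`, `element`,
#'   `freq_lp_mm`, `bar_w_px`, `bar_len_px`, and the top-left corner
#'   `(y0, x0)` of its three-vertical-bar block (0-based pixel coords).
#' @export
usaf_layout <- function(groups, scale_px_per_mm) {
  margin <- 24
  rows <- list()
  x <- margin
  for (g in sort(groups)) {
    y <- margin
    gw <- 0
    for (e in 1:6) {
      f <- usaf_frequency(g, e)
      w <- scale_px_per_mm * 0.5 / f       # bar width: half a line pair
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, element = e, freq_lp_mm = f,
        bar_w_px = w, bar_len_px = 5 * w, y0 = y, x0 = x)
      y <- y + 5 * w + max(2 * w, 6)
      gw <- max(gw, 5 * w)
    }
    x <- x + gw + margin
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "margin") <- margin
  out
}

#' Spatial frequency of a USAF element
#'
#' `2^(group + (element - 1) / 6)` line pairs per millimetre.
#'
#' @param group Group number (integer, may be negative).
#' @param element Element number 1-6.
#' @return Frequency in lp/mm.
#' @export
usaf_frequency <- function(group, element) {
  stopifnot(all(element %in% 1:6))
  2^(group + (element - 1) / 6)
}

#' Color-checker chart scene
#'
#' The classic 24-patch chart (4 rows x 6 columns). With the default
#' `rate`, a 10 ms exposure at unit gain reproduces each patch's 8-bit sRGB
#' value in counts, so chart accuracy can be scored directly against the
#' published values.
#'
#' @param patch_px Patch side length (px).
#' @param gap_px Gap between patches (px).
#' @param rate_scale Signal rate per sRGB count (counts/ms per 8-bit level).
#' @return An object of class `color_checker_scene`; `$patches` maps patch
#'   names to reference sRGB values and regions.
#' @export
color_checker_scene <- function(patch_px = 40, gap_px = 10, rate_scale = 0.1) {
  ref <- color_checker_reference()
  ref$prow <- (ref$index - 1) %/% 6
  ref$pcol <- (ref$index - 1) %% 6
  ref$y0 <- gap_px + ref$prow * (patch_px + gap_px)
  ref$x0 <- gap_px + ref$pcol * (patch_px + gap_px)
  H <- gap_px + 4 * (patch_px + gap_px)
  W <- gap_px + 6 * (patch_px + gap_px)
  structure(list(patches = ref, patch_px = patch_px, gap_px = gap_px,
                 rate_scale = rate_scale, dim = c(H, W)),
            class = c("color_checker_scene", "scene"))
}

#' Reference sRGB values of the classic 24-patch color checker
#'
#' @return Tibble with `index`, `name`, `r`, `g`, `b` (8-bit sRGB).
#' @export
color_checker_reference <- function() {
  tibble::tibble(
    index = 1:24,
    name = c("dark skin", "light skin", "blue sky", "foliage", "blue flower",
             "bluish green", "orange", "purplish blue", "moderate red",
             "purple", "yellow green", "orange yellow", "blue", "green",
             "red", "yellow", "magenta", "cyan", "white", "neutral 8",
             "neutral 6.5", "neutral 5", "neutral 3.5", "black"),
    r = c(115, 194, 98, 87, 133, 103, 214, 80, 193, 94, 157, 224, 56, 70,
          175, 231, 187, 8, 243, 200, 160, 122, 85, 52),
    g = c(82, 150, 122, 108, 128, 189, 126, 91, 90, 60, 188, 163, 61, 148,
          54, 199, 86, 133, 243, 200, 160, 122, 85, 52),
    b = c(68, 130, 157, 67, 177, 170, 44, 166, 99, 108, 64, 46, 150, 73,
          60, 31, 149, 161, 242, 200, 160, 121, 85, 52))
}

#' Dot-grid distortion chart scene
#'
#' A square lattice of Gaussian dots centered on the image center, warped by
#' a single-coefficient radial model `r' = r (1 + k1 r^2)`. Used to verify
#' that [distortion_check()] recovers an injected coefficient.
#'
#' @param n_dots Dots per side (odd, so one dot sits at the center).
#' @param pitch_px Lattice pitch (px).
#' @param dot_sigma_px Gaussian dot SD (px).
#' @param k1 Injected radial coefficient (1/px^2; negative = barrel).
#' @param rate Peak dot signal rate (counts/ms).
#' @param margin_px Canvas margin (px).
#' @return An object of class `distortion_grid_scene`.
#' @export
distortion_grid_scene <- function(n_dots = 9, pitch_px = 60, dot_sigma_px = 2,
                                  k1 = 0, rate = 20, margin_px = 50) {
  if (n_dots %% 2 == 0) stop("n_dots must be odd")
  side <- (n_dots - 1) * pitch_px + 2 * margin_px + 1
  structure(list(n_dots = n_dots, pitch_px = pitch_px,
                 dot_sigma_px = dot_sigma_px, k1 = k1, rate = rate,
                 dim = c(side, side)),
            class = c("distortion_grid_scene", "scene"))
}

#' Mineral specimen scene
#'
#' Rectangular regions, each emitting a discrete spectrum with its own
#' brightness, on a dark background — the scene behind long-pass
#' filter-series spectral analysis.
#'
#' @param regions List of `list(label =, row0 =, row1 =, col0 =, col1 =,
#'   emission = data.frame(lambda_nm, weight), rate = counts/ms)`.
#' @param dim Canvas `c(H, W)`.
#' @return An object of class `mineral_scene`.
#' @export
mineral_scene <- function(regions, dim = c(240, 360)) {
  structure(list(regions = regions, dim = dim),
            class = c("mineral_scene", "scene"))
}

#' Single-specimen scene (one time point of a growth series)
#'
#' A bright ellipse on a dark background; time-lapse presets chain several
#' of these with increasing axes.
#'
#' @param a_px,b_px Ellipse semi-axes (px).
#' @param center `c(row, col)`; defaults to the canvas center.
#' @param angle_deg Major-axis orientation.
#' @param fg_rate,bg_rate Foreground/background signal rates (counts/ms).
#' @param dim Canvas `c(H, W)`.
#' @return An object of class `specimen_scene`.
#' @export
specimen_scene <- function(a_px, b_px, center = NULL, angle_deg = 0,
                           fg_rate = 12, bg_rate = 0.5, dim = c(240, 320)) {
  if (a_px <= 0 || b_px <= 0) stop("semi-axes must be > 0")
  if (is.null(center)) center <- (dim - 1) / 2
  structure(list(a_px = a_px, b_px = b_px, center = center,
                 angle_deg = angle_deg, fg_rate = fg_rate, bg_rate = bg_rate,
                 dim = dim),
            class = c("specimen_scene", "scene"))
}

#' Radial vignetting field
#'
#' `1 - amplitude * (r / r_corner)^2` about the image center: 1 at the
#' center, `1 - amplitude` at the corners.
#'
#' @param dim `c(H, W)`.
#' @param amplitude Fractional fall-off at the corner.
#' @return H x W multiplier matrix.
#' @export
radial_vignette <- function(dim, amplitude) {
  H <- dim[1]; W <- dim[2]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  r2 <- outer((seq_len(H) - 1 - cy)^2, (seq_len(W) - 1 - cx)^2, `+`)
  1 - amplitude * r2 / (cy^2 + cx^2)
}
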