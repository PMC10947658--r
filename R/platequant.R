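#' Microplate layout
#'
#' Logical plate geometry: a regular lattice of circular wells. Labels run
#' row-major from A1 at the top-left (A1..H12 for a 96-well plate).
#'
#' @param n_rows,n_cols Plate format (default 8 x 12 = 96 wells).
#' @param pitch_px Center-to-center well spacing (px).
#' @param radius_px Well radius (px); must leave a guard gap
#'   (`pitch > 2.2 * radius`).
#' @param origin_px `c(row, col)` of the A1 well center (0-based px).
#' @return An object of class `plate_layout`; `$image_dim` is the natural
#'   canvas size (origin-sized margins on all sides).
#' @export
plate_layout <- function(n_rows = 8, n_cols = 12, pitch_px = 40,
                         radius_px = 14, origin_px = c(40, 40)) {
  if (pitch_px <= 2.2 * radius_px)
    stop("well pitch must exceed 2.2 * radius (overlap guard)")
  dim <- c(2 * origin_px[1] + (n_rows - 1) * pitch_px,
           2 * origin_px[2] + (n_cols - 1) * pitch_px)
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch_px = pitch_px,
                 radius_px = radius_px, origin_px = origin_px,
                 image_dim = dim),
            class = "plate_layout")
}

well_label <- function(row, col) paste0(LETTERS[row], col)

#' Nominal well centers of a plate layout
#'
#' @param layout A [plate_layout()].
#' @return Tibble: `well`, `label`, `row`, `col`, `center_row`, `center_col`.
#' @export
plate_centers <- function(layout) {
  g <- expand.grid(col = seq_len(layout$n_cols), row = seq_len(layout$n_rows))
  g <- g[order(g$row, g$col), ]
  tibble::tibble(
    well = seq_len(nrow(g)),
    label = well_label(g$row, g$col),
    row = g$row, col = g$col,
    center_row = layout$origin_px[1] + (g$row - 1) * layout$pitch_px,
    center_col = layout$origin_px[2] + (g$col - 1) * layout$pitch_px)
}

#' Detect the well grid in a plate image
#'
#' With a layout: nominal lattice centers are refined by local intensity
#' centroid within `pitch / 4`. Without a layout: lattice pitch is estimated
#' from the autocorrelation of background-subtracted row/column mean
#' profiles and the phase by comb matching, assuming the default 8 x 12
#' format; centers are then refined the same way. Wells whose refinement
#' diverges (no signal mass, or a shift beyond `pitch / 4`) fall back to the
#' lattice position; if more than 10% diverge the grid is rejected.
#'
#' @param frame An [image_frame()].
#' @param layout Optional [plate_layout()].
#' @param channel Channel used for detection.
#' @return A `well_grid`: tibble `well`, `label`, `row`, `col`,
#'   `center_row`, `center_col`, `refined`; attributes `layout`.
#' @export
detect_grid <- function(frame, layout = NULL, channel = "G") {
  m <- channel_matrix(frame, channel)
  if (is.null(layout)) layout <- estimate_layout(m)
  centers <- plate_centers(layout)
  bg <- stats::median(m)
  half <- floor(layout$pitch_px / 4)
  refined <- logical(nrow(centers))
  empty <- logical(nrow(centers))    # no signal mass: fall back to lattice
  diverged <- logical(nrow(centers)) # centroid ran off: suspicious
  for (w in seq_len(nrow(centers))) {
    r0 <- round(centers$center_row[w]); c0 <- round(centers$center_col[w])
    rr <- max(1, r0 + 1 - half):min(nrow(m), r0 + 1 + half)
    cc <- max(1, c0 + 1 - half):min(ncol(m), c0 + 1 + half)
    wts <- pmax(m[rr, cc, drop = FALSE] - bg, 0)
    tot <- sum(wts)
    if (tot <= 1e-6) { empty[w] <- TRUE; next }
    cr <- sum(rowSums(wts) * (rr - 1)) / tot
    ccol <- sum(colSums(wts) * (cc - 1)) / tot
    if (abs(cr - centers$center_row[w]) > layout$pitch_px / 4 ||
        abs(ccol - centers$center_col[w]) > layout$pitch_px / 4) {
      diverged[w] <- TRUE; next
    }
    centers$center_row[w] <- cr
    centers$center_col[w] <- ccol
    refined[w] <- TRUE
  }
  if (all(!refined) || mean(diverged) > 0.10) stop("grid not found")
  centers$refined <- refined
  structure(centers, layout = layout, class = c("well_grid", class(centers)))
}

# pitch from profile autocorrelation, phase by comb matching (8 x 12 assumed)
estimate_layout <- function(m, n_rows = 8, n_cols = 12) {
  pitch_of <- function(prof) {
    prof <- prof - mean(prof)
    ac <- stats::acf(prof, lag.max = floor(length(prof) / 2),
                     plot = FALSE)$acf[, 1, 1]
    # first local maximum beyond the zero-lag peak
    for (lag in 4:(length(ac) - 2)) {
      if (ac[lag + 1] > 0 && ac[lag + 1] >= ac[lag] && ac[lag + 1] >= ac[lag + 2])
        return(lag)
    }
    stop("grid not found")
  }
  phase_of <- function(prof, pitch, n) {
    # scan every origin that keeps the whole lattice inside the profile
    max_o <- length(prof) - (n - 1) * pitch - 1
    if (max_o < 0) stop("grid not found")
    best <- -Inf; arg <- 0
    for (off in 0:max_o) {
      sc <- sum(prof[off + pitch * (0:(n - 1)) + 1])
      if (sc > best) { best <- sc; arg <- off }
    }
    arg
  }
  pr <- rowMeans(m); pc <- colMeans(m)
  pitch_r <- pitch_of(pr); pitch_c <- pitch_of(pc)
  pitch <- round((pitch_r + pitch_c) / 2)
  plate_layout(n_rows, n_cols, pitch_px = pitch,
               radius_px = max(3, round(0.35 * pitch)),
               origin_px = c(phase_of(pr, pitch_r, n_rows),
                             phase_of(pc, pitch_c, n_cols)))
}

#' Per-well mean intensities
#'
#' Mean counts over a disk of radius `r_frac * well radius` at each detected
#' center (the inner disk avoids edge reflections at the well wall). With
#' `background = "annulus"`, the median of an annulus at 1.2-1.5 well radii
#' is subtracted per well and results are floored at 0. Wells whose disk is
#' clipped by the image edge are flagged but still measured.
#'
#' @param frame An [image_frame()].
#' @param grid A `well_grid` from [detect_grid()].
#' @param channel Channel to quantify.
#' @param background `"none"` or `"annulus"`.
#' @param r_frac Measurement-disk radius as a fraction of the well radius.
#' @return Tibble: `well`, `label`, `row`, `col`, `value`, `edge_clipped`.
#' @export
well_intensities <- function(frame, grid, channel = "G",
                             background = c("none", "annulus"),
                             r_frac = 0.8) {
  background <- match.arg(background)
  layout <- attr(grid, "layout")
  m <- channel_matrix(frame, channel)
  H <- nrow(m); W <- ncol(m)
  r_in <- r_frac * layout$radius_px
  r_an <- c(1.2, 1.5) * layout$radius_px
  out <- grid[, c("well", "label", "row", "col")]
  value <- numeric(nrow(grid)); clipped <- logical(nrow(grid))
  for (w in seq_len(nrow(grid))) {
    cr <- grid$center_row[w]; cc <- grid$center_col[w]
    ext <- r_an[2]
    rr <- max(1, floor(cr - ext) + 1):min(H, ceiling(cr + ext) + 1)
    cc2 <- max(1, floor(cc - ext) + 1):min(W, ceiling(cc + ext) + 1)
    d2 <- outer(((rr - 1) - cr)^2, ((cc2 - 1) - cc)^2, `+`)
    disk <- d2 <= r_in^2
    clipped[w] <- (cr - r_in < 0) || (cr + r_in > H - 1) ||
      (cc - r_in < 0) || (cc + r_in > W - 1)
    v <- mean(m[rr, cc2][disk])
    if (background == "annulus") {
      ann <- d2 >= r_an[1]^2 & d2 <= r_an[2]^2
      v <- max(v - stats::median(m[rr, cc2][ann]), 0)
    }
    value[w] <- v
  }
  dplyr::mutate(tibble::as_tibble(out), value = value, edge_clipped = clipped)
}

#' Per-well percent deviation from the plate average
#'
#' `dev_i = 100 * (v_i - mean(v)) / mean(v)`; the deviations always sum to
#' zero. The flatness figure of merit is the maximum absolute deviation,
#' attached as attribute `max_abs_pct`.
#'
#' @param values Numeric vector of well values, or a data frame with a
#'   `value` column (e.g. from [well_intensities()]).
#' @return Tibble with a `deviation_pct` column; attribute `max_abs_pct`.
#' @export
percent_deviation <- function(values) {
  if (is.data.frame(values)) {
    v <- values$value
    out <- tibble::as_tibble(values)
  } else {
    v <- as.numeric(values)
    out <- tibble::tibble(value = v)
  }
  if (length(v) < 2) stop("need at least 2 wells")
  mu <- mean(v)
  if (mu <= 0) stop("plate mean must be > 0")
  out$deviation_pct <- 100 * (v - mu) / mu
  attr(out, "max_abs_pct") <- max(abs(out$deviation_pct))
  out
}

#' Flat-field correction
#'
#' Divides the frame by a normalized illumination-field estimate:
#' `corrected = frame * mean(field) / field`, clipped to the valid count
#' range.
#'
#' @param frame An [image_frame()].
#' @param field Strictly positive H x W multiplier field.
#' @return Corrected [image_frame()].
#' @export
flat_field_correct <- function(frame, field) {
  stopifnot(is.matrix(field))
  if (!identical(dim(field), dim(frame$pixels)[1:2]))
    stop("field size must match frame")
  if (any(field <= 0)) stop("field must be strictly positive")
  corr <- mean(field) / field
  px <- frame$pixels
  for (ch in 1:3) px[, , ch] <- px[, , ch] * corr
  px <- pmin(pmax(px, 0), frame_saturation(frame))
  image_frame(px, bit_depth = frame$bit_depth, setting = frame$setting,
              pixel_pitch_um = frame$pixel_pitch_um)
}
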