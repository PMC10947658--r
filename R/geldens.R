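#' Lane densitometry profile
#'
#' Per-row mean intensity across a lane box (the box must be taller than
#' wide: rows are the run direction). Background is removed by a rolling
#' minimum along the profile (window 50 px by default), floored at 0; use
#' `background = "none"` for the raw profile.
#'
#' @param frame An [image_frame()].
#' @param lane_box A [region_box()] covering one lane.
#' @param channel Channel to quantify.
#' @param background `"rolling_min"` or `"none"`.
#' @param window_px Rolling-minimum window (px).
#' @param label,load Metadata carried on the profile.
#' @return A `lane_profile`: tibble `distance_px`, `intensity` with
#'   attributes `label`, `load`.
#' @export
lane_profile <- function(frame, lane_box, channel = "gray",
                         background = c("rolling_min", "none"),
                         window_px = 50, label = lane_box$label, load = NA) {
  background <- match.arg(background)
  if (lane_box$type != "box") stop("lane_box must be a region_box")
  if ((lane_box$row1 - lane_box$row0) <= (lane_box$col1 - lane_box$col0))
    stop("lane box must be taller than wide")
  idx <- region_index(frame, lane_box)   # also bounds-checks
  m <- channel_matrix(frame, channel)
  rows <- sort(unique(idx[, 1]))
  cols <- sort(unique(idx[, 2]))
  prof <- rowMeans(m[rows, cols, drop = FALSE])
  if (background == "rolling_min") prof <- pmax(prof - rolling_min(prof, window_px), 0)
  structure(tibble::tibble(distance_px = rows - 1 - lane_box$row0,
                           intensity = prof),
            label = label, load = load,
            class = c("lane_profile", class(tibble::tibble())))
}

# rolling minimum with edge-truncated windows
rolling_min <- function(x, window) {
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i)
    min(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

# prominence of a local maximum: height above the higher of the two key
# saddles (lowest point between the peak and the nearest higher ground on
# each side; profile ends count as higher ground at -Inf)
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p - 1)]
    right <- if (p < length(y)) y[(p + 1):length(y)] else numeric(0)
    higher_l <- which(left >= y[p])
    base_l <- if (length(higher_l)) min(y[(max(higher_l)):p]) else min(c(left, y[p]))
    higher_r <- which(right >= y[p])
    base_r <- if (length(higher_r))
      min(y[p:(p + min(higher_r))]) else min(c(right, y[p]))
    y[p] - max(base_l, base_r)
  }, numeric(1))
}

#' Detect bands in a lane profile
#'
#' Local maxima whose prominence reaches `prominence_frac` of the profile
#' range; each band's area is the trapezoidal integral between its flanking
#' minima (profile ends for the outermost bands). A flat profile yields
#' zero bands.
#'
#' @param profile A `lane_profile` (or tibble with `distance_px`,
#'   `intensity`).
#' @param prominence_frac Prominence threshold as a fraction of the range.
#' @return Tibble: `band`, `position_px`, `height`, `prominence`,
#'   `area` (counts x px), `from_px`, `to_px`.
#' @export
detect_bands <- function(profile, prominence_frac = 0.05) {
  y <- profile$intensity
  x <- profile$distance_px
  if (length(y) < 10) stop("profile too short")
  rng <- max(y) - min(y)
  empty <- tibble::tibble(band = integer(), position_px = numeric(),
                          height = numeric(), prominence = numeric(),
                          area = numeric(), from_px = numeric(),
                          to_px = numeric())
  if (rng == 0) return(empty)
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  peaks <- which(is_max)
  if (length(peaks) == 0) return(empty)
  prom <- peak_prominence(y, peaks)
  keep <- prom >= prominence_frac * rng
  peaks <- peaks[keep]; prom <- prom[keep]
  if (length(peaks) == 0) return(empty)
  # flanking minima: lowest point between consecutive kept peaks
  bounds <- c(1, vapply(seq_len(length(peaks) - 1), function(i) {
    seg <- peaks[i]:peaks[i + 1]
    seg[which.min(y[seg])]
  }, numeric(1)), n)
  area <- vapply(seq_along(peaks), function(i) {
    seg <- bounds[i]:bounds[i + 1]
    pracma::trapz(x[seg], y[seg])
  }, numeric(1))
  tibble::tibble(band = seq_along(peaks), position_px = x[peaks],
                 height = y[peaks], prominence = prom, area = area,
                 from_px = x[bounds[seq_along(peaks)]],
                 to_px = x[bounds[seq_along(peaks) + 1]])
}

#' Fit the semilog migration model
#'
#' Least squares `position = a - b * log10(size)`; `b > 0` encodes that
#' smaller fragments travel farther. Warns when band positions are not
#' monotone in size.
#'
#' @param band_positions_px Band positions (px from the well).
#' @param sizes_bp Fragment sizes (bp), same length, >= 3.
#' @return Object of class `migration_model`: `a`, `b`, `r_squared`, `fit`.
#' @export
migration_fit <- function(band_positions_px, sizes_bp) {
  if (length(band_positions_px) < 3 ||
      length(sizes_bp) != length(band_positions_px))
    stop("need at least 3 bands with known sizes")
  ord <- order(sizes_bp)
  if (is.unsorted(rev(band_positions_px[ord])))
    warning("band positions are not monotone in fragment size")
  lsize <- log10(sizes_bp)
  fit <- stats::lm(band_positions_px ~ lsize)
  structure(list(a = unname(stats::coef(fit)[1]),
                 b = -unname(stats::coef(fit)[2]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit),
            class = "migration_model")
}

#' Predict band position from fragment size
#'
#' @param object A `migration_model`.
#' @param sizes_bp Fragment sizes (bp).
#' @param ... Unused.
#' @return Positions in px.
#' @export
predict.migration_model <- function(object, sizes_bp, ...) {
  object$a - object$b * log10(sizes_bp)
}

#' Compare two lane profiles
#'
#' Total-intensity ratio (lane 2 over lane 1) plus per-band ratios for
#' bands matched greedily to the nearest counterpart within a position
#' tolerance. When either lane has no detectable bands only the total ratio
#' is returned.
#'
#' @param p1,p2 `lane_profile`s on the same length scale.
#' @param match_tol_px Band-matching tolerance (px).
#' @param prominence_frac Passed to [detect_bands()].
#' @return List: `total_ratio`, `bands` (tibble `position_1`, `position_2`,
#'   `area_1`, `area_2`, `ratio`), `unmatched_1`, `unmatched_2`.
#' @export
compare_lanes <- function(p1, p2, match_tol_px = 5, prominence_frac = 0.05) {
  total_ratio <- sum(p2$intensity) / sum(p1$intensity)
  b1 <- detect_bands(p1, prominence_frac)
  b2 <- detect_bands(p2, prominence_frac)
  if (nrow(b1) == 0 || nrow(b2) == 0)
    return(list(total_ratio = total_ratio, bands = NULL,
                unmatched_1 = nrow(b1), unmatched_2 = nrow(b2)))
  taken <- rep(FALSE, nrow(b2))
  rows <- list()
  for (i in seq_len(nrow(b1))) {
    dist <- abs(b2$position_px - b1$position_px[i])
    dist[taken] <- Inf
    j <- which.min(dist)
    if (dist[j] <= match_tol_px) {
      taken[j] <- TRUE
      rows[[length(rows) + 1]] <- tibble::tibble(
        position_1 = b1$position_px[i], position_2 = b2$position_px[j],
        area_1 = b1$area[i], area_2 = b2$area[j],
        ratio = b2$area[j] / b1$area[i])
    }
  }
  bands <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  list(total_ratio = total_ratio, bands = bands,
       unmatched_1 = nrow(b1) - length(rows),
       unmatched_2 = nrow(b2) - sum(taken))
}
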