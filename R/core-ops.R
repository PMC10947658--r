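#' Per-channel mean and standard deviation of an image stack
#'
#' Pools all pixels of all frames per channel, as used for dark-frame
#' black-level characterization. The standard deviation is the population
#' (divide-by-N) form and pools spatial and temporal variation together.
#'
#' @param stack An [image_stack()].
#' @return A tibble with columns `channel` (`"R"`, `"G"`, `"B"`), `mean`,
#'   `sd` (counts) and `n_pixels`.
#' @export
stack_mean_std <- function(stack) {
  if (!inherits(stack, "image_stack")) stop("stack must be an image_stack")
  if (length(stack$frames) == 0) stop("empty stack")
  sums <- numeric(3); sqsums <- numeric(3); n <- 0
  for (f in stack$frames) {
    for (ch in 1:3) {
      v <- f$pixels[, , ch]
      sums[ch] <- sums[ch] + sum(v)
      sqsums[ch] <- sqsums[ch] + sum(v^2)
    }
    n <- n + prod(dim(f$pixels)[1:2])
  }
  mu <- sums / n
  varp <- pmax(sqsums / n - mu^2, 0)
  tibble::tibble(channel = c("R", "G", "B"), mean = mu, sd = sqrt(varp),
                 n_pixels = n)
}

#' Mean intensity over a region
#'
#' @param frame An [image_frame()].
#' @param region A [region_box()] or [region_mask()].
#' @param channel `"R"`, `"G"`, `"B"` or `"gray"` (Rec.601 luma).
#' @param gray_weights Luma weights used for `channel = "gray"`.
#' @return Mean counts (scalar).
#' @export
region_intensity <- function(frame, region, channel = "G",
                             gray_weights = c(0.299, 0.587, 0.114)) {
  idx <- region_index(frame, region)
  if (nrow(idx) == 0) stop("empty region")
  m <- channel_matrix(frame, channel, gray_weights)
  mean(m[idx])
}

#' Convert an RGB frame to grayscale
#'
#' Weighted channel sum with Rec.601 luma weights by default
#' (`0.299 R + 0.587 G + 0.114 B`); no rounding is applied.
#'
#' @param frame An [image_frame()].
#' @param weights Length-3 channel weights.
#' @return H x W numeric matrix of gray counts.
#' @export
to_gray <- function(frame, weights = c(0.299, 0.587, 0.114)) {
  stopifnot(length(weights) == 3)
  p <- frame$pixels
  weights[1] * p[, , 1] + weights[2] * p[, , 2] + weights[3] * p[, , 3]
}

# bilinear interpolation of a matrix at fractional 0-based (row, col)
# coordinates; pixel centers at integers, edge-clamped
bilinear_at <- function(m, row, col) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(row, 0), H - 1)
  cc <- pmin(pmax(col, 0), W - 1)
  r0 <- floor(r); c0 <- floor(cc)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- r - r0; fc <- cc - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c1 + 1)
  i10 <- cbind(r1 + 1, c0 + 1); i11 <- cbind(r1 + 1, c1 + 1)
  (1 - fr) * (1 - fc) * m[i00] + (1 - fr) * fc * m[i01] +
    fr * (1 - fc) * m[i10] + fr * fc * m[i11]
}

#' Intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation at (close to) unit-pixel
#' spacing along the segment from `start` to `end`. Both endpoints are
#' included; for a segment of length `L` pixels the profile has
#' `ceiling(L) + 1` samples spaced `L / ceiling(L)` apart.
#'
#' @param frame An [image_frame()].
#' @param start,end Numeric `c(row, col)` endpoints, 0-based pixel-center
#'   coordinates.
#' @param channel `"R"`, `"G"`, `"B"` or `"gray"`.
#' @return A tibble with columns `distance_px` and `intensity`.
#' @export
line_profile <- function(frame, start, end, channel = "gray") {
  d <- dim(frame$pixels)
  pts <- rbind(start, end)
  if (any(pts[, 1] < 0) || any(pts[, 1] > d[1] - 1) ||
      any(pts[, 2] < 0) || any(pts[, 2] > d[2] - 1))
    stop("profile endpoints outside image")
  L <- sqrt(sum((end - start)^2))
  n <- max(ceiling(L), 1)
  t <- seq(0, 1, length.out = n + 1)
  if (L == 0) t <- 0
  rows <- start[1] + t * (end[1] - start[1])
  cols <- start[2] + t * (end[2] - start[2])
  m <- channel_matrix(frame, channel)
  tibble::tibble(distance_px = t * L, intensity = bilinear_at(m, rows, cols))
}
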