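#' Camera model
#'
#' RGB sensor model behind the virtual instrument: per-channel black level
#' (offset counts), Gaussian read noise, optional Poisson shot noise on the
#' amplified signal, and a smooth per-channel spectral response. Output
#' counts are clipped to `[0, 2^bit_depth - 1]`.
#'
#' @param bit_depth Sensor bit depth (default 8, the PNG path; 16 supported
#'   for headroom work).
#' @param black_level Length-3 offset counts (R, G, B).
#' @param read_noise_sd Length-3 Gaussian read-noise SD in counts.
#' @param gain Counts per photon-equivalent signal unit (> 0).
#' @param shot_noise If `TRUE`, Poisson noise is applied to `gain * signal`.
#' @param channel_response Function `f(lambda_nm)` returning a length-3 (or
#'   `3 x n`) relative quantum efficiency for the R, G, B channels. The
#'   default is a trio of Gaussian response curves peaking at 610, 540 and
#'   465 nm.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(bit_depth = 8,
                         black_level = c(0, 0, 0),
                         read_noise_sd = c(0, 0, 0),
                         gain = 1,
                         shot_noise = FALSE,
                         channel_response = default_channel_response) {
  stopifnot(length(black_level) == 3, length(read_noise_sd) == 3)
  if (any(read_noise_sd < 0)) stop("read_noise_sd must be >= 0")
  if (gain <= 0) stop("gain must be > 0")
  structure(list(bit_depth = bit_depth, black_level = black_level,
                 read_noise_sd = read_noise_sd, gain = gain,
                 shot_noise = shot_noise, channel_response = channel_response,
                 saturation = 2^bit_depth - 1),
            class = "camera_model")
}

#' Default RGB channel spectral response
#'
#' Gaussian relative QE curves: R centered 610 nm (sd 45), G centered
#' 540 nm (sd 40), B centered 465 nm (sd 35), each peaking at 1.
#'
#' @param lambda_nm Wavelengths (nm).
#' @return A `3 x length(lambda_nm)` matrix (rows R, G, B).
#' @export
default_channel_response <- function(lambda_nm) {
  rbind(R = exp(-(lambda_nm - 610)^2 / (2 * 45^2)),
        G = exp(-(lambda_nm - 540)^2 / (2 * 40^2)),
        B = exp(-(lambda_nm - 465)^2 / (2 * 35^2)))
}

#' LED board model
#'
#' Three addressable excitation channels (blue 460 nm, green 520 nm, red
#' 630 nm) plus an external UV port. Optical power versus drive level is a
#' monotone map with `power(0) = 0` (linear by default); irradiance versus
#' distance is a decreasing map (inverse-square by default).
#'
#' @param power_vs_drive Monotone nondecreasing function on `[0, 1]` with
#'   `f(0) = 0`, shared by all channels (relative units, `f(1) = 1` for the
#'   default).
#' @param irradiance_vs_distance Decreasing function of distance (relative).
#' @return An object of class `led_model`.
#' @export
led_model <- function(power_vs_drive = function(d) d,
                      irradiance_vs_distance = function(x) 1 / x^2) {
  structure(list(
    peaks_nm = c(blue_460 = 460, green_520 = 520, red_630 = 630,
                 external_uv = 395),
    power_vs_drive = power_vs_drive,
    irradiance_vs_distance = irradiance_vs_distance),
    class = "led_model")
}

# relative excitation power delivered by a setting's LED channel
led_power <- function(led, setting) {
  if (setting$led_channel == "off") return(0)
  if (!setting$led_channel %in% names(led$peaks_nm))
    stop("unknown LED channel: ", setting$led_channel)
  led$power_vs_drive(setting$drive_level)
}

#' Fluorophore model
#'
#' A discrete-line emitter: per-LED-channel excitation efficiency, an
#' emission spectrum given as wavelength/weight pairs (weights sum to 1), a
#' brightness constant `k` in counts per molar per millisecond at unit
#' drive (pre-saturation), and an inner-filter product `epsilon_l`
#' (molar absorptivity times path length, per molar) controlling
#' high-concentration roll-off.
#'
#' @param name Label.
#' @param excitation Named vector of efficiencies in `[0, 1]` keyed by LED
#'   channel; missing channels are 0.
#' @param emission Data frame with columns `lambda_nm`, `weight`; weights
#'   are normalized to sum to 1.
#' @param k Brightness constant (counts / M / ms), > 0.
#' @param epsilon_l Inner-filter product (1 / M), >= 0.
#' @return An object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(name, excitation, emission, k, epsilon_l = 0) {
  stopifnot(k > 0, epsilon_l >= 0)
  emission <- as.data.frame(emission)
  if (any(emission$weight < 0)) stop("emission weights must be >= 0")
  emission$weight <- emission$weight / sum(emission$weight)
  structure(list(name = name, excitation = excitation, emission = emission,
                 k = k, epsilon_l = epsilon_l),
            class = "fluorophore_model")
}

#' FITC-like fluorophore preset
#'
#' Blue-excited (460 nm LED, efficiency 1), single emission line at 520 nm.
#' The inner-filter product defaults to 22500 / M (a molar absorptivity of
#' 75,000 / M / cm over a 0.3 cm path, typical of 200 uL in a PCR well).
#'
#' @param k Brightness constant (counts / M / ms).
#' @param epsilon_l Inner-filter product (1 / M).
#' @return A [fluorophore_model()].
#' @export
fluor_fitc <- function(k = 1e10, epsilon_l = 22500) {
  fluorophore_model("FITC", c(blue_460 = 1),
                    data.frame(lambda_nm = 520, weight = 1),
                    k = k, epsilon_l = epsilon_l)
}

#' Inner-filter saturation factor
#'
#' `f_sat(c) = (1 - 10^(-epsilon_l * c)) / (epsilon_l * c * ln 10)`,
#' a strictly decreasing function of concentration with `f_sat -> 1` as
#' `c -> 0`. Supplies the phenomenological high-concentration roll-off of
#' dilution-series response curves without modelling quenching.
#'
#' @param c_molar Concentration (M), >= 0.
#' @param epsilon_l Inner-filter product (1 / M).
#' @return Saturation factor in `(0, 1]`.
#' @export
f_sat <- function(c_molar, epsilon_l) {
  x <- epsilon_l * c_molar
  out <- rep(1, length(x))
  big <- x > 1e-9
  out[big] <- (1 - 10^(-x[big])) / (x[big] * log(10))
  # series expansion 1 - x ln10 / 2 for tiny arguments avoids cancellation
  out[!big] <- 1 - x[!big] * log(10) / 2
  out
}

# per-channel detected weight of a fluorophore's emission through a filter:
# sum_lambda w * pass(lambda) * QE_channel(lambda); length-3 (R, G, B)
emission_channel_weight <- function(fluor, filter, camera) {
  lam <- fluor$emission$lambda_nm
  w <- fluor$emission$weight * filter_pass(filter, lam)
  qe <- camera$channel_response(lam)
  if (is.null(dim(qe))) qe <- matrix(qe, nrow = 3)
  as.numeric(qe %*% w)
}

#' Moments of a zero-clipped Gaussian
#'
#' Mean and SD of `max(X, 0)` for `X ~ N(mu, sigma)` — the closed-form
#' moments of the dark-frame noise model.
#'
#' @param mu,sigma Underlying normal parameters (`sigma > 0`).
#' @return Named vector `c(mean, sd)`.
#' @export
clipped_normal_moments <- function(mu, sigma) {
  a <- mu / sigma
  m1 <- mu * stats::pnorm(a) + sigma * stats::dnorm(a)
  m2 <- (mu^2 + sigma^2) * stats::pnorm(a) + mu * sigma * stats::dnorm(a)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

#' Invert the zero-clipped Gaussian moment equations
#'
#' Finds underlying `(mu, sigma)` whose zero-clipped moments match a target
#' observed mean and SD, e.g. to moment-match a camera's published
#' dark-frame statistics.
#'
#' @param target_mean,target_sd Observed clipped mean and SD (counts).
#' @return Named vector `c(mu, sigma)`.
#' @export
match_clipped_normal <- function(target_mean, target_sd) {
  stopifnot(target_mean > 0, target_sd > 0)
  obj <- function(p) {
    m <- clipped_normal_moments(p[1], exp(p[2]))
    (m[1] - target_mean)^2 + (m[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-8) stop("clipped-normal moment matching did not converge")
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}
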