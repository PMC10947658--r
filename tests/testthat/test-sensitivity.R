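tiny_sweep_curve <- function() {
  # noise-free 3-exposure sweep over four decades
  lay <- plate_layout()
  conc <- matrix(0, 8, 12)
  conc[1:3, 1:4] <- matrix(10^-(6:9), 3, 4, byrow = TRUE)
  scene <- plate_scene(lay, conc, fluor_fitc(k = 1e8, epsilon_l = 0))
  sw <- render_sweep(scene, lapply(c(1, 10, 100), blue_setting),
                     quiet_camera(), led_model())
  pm <- rbind(
    tibble::tibble(label = well_label(rep(1:3, each = 4), rep(1:4, 3)),
                   concentration = rep(10^-(6:9), 3)),
    tibble::tibble(label = well_label(4, 1:6), concentration = 0))
  g <- detect_grid(sw$frames[[3]], lay)
  build_curves(sw, g, pm)
}

test_that("curve building groups replicates per concentration per exposure", {
  cur <- tiny_sweep_curve()
  expect_equal(sort(unique(cur$data$exposure_ms)), c(1, 10, 100))
  expect_true(all(cur$data$n == 3))
  expect_true(all(cur$data$sd == 0))          # identical replicates, no noise
  expect_equal(nrow(cur$blanks), 3)

  # noise off: means match the closed-form forward model within 1%
  qe_g <- exp(-(520 - 540)^2 / (2 * 40^2))
  d <- cur$data
  expected <- pmin(1e8 * d$concentration * d$exposure_ms * qe_g, 255)
  unsat <- expected < 230
  expect_true(all(abs(d$mean[unsat] - expected[unsat]) /
                    pmax(expected[unsat], 1e-9) < 0.01))
})

test_that("curve building demands blanks and exposure metadata", {
  lay <- plate_layout()
  scene <- plate_scene(lay, 1e-6, fluor_fitc(k = 2e7))
  sw <- render_sweep(scene, list(blue_setting(10)), quiet_camera())
  g <- detect_grid(sw$frames[[1]], lay)
  no_blank <- tibble::tibble(label = c("A1", "A2"), concentration = 1e-6)
  expect_error(build_curves(sw, g, no_blank), "no blank")

  sw$frames[[1]]$setting <- NULL
  pm <- tibble::tibble(label = c("A1", "H12"), concentration = c(1e-6, 0))
  expect_error(build_curves(sw, g, pm), "missing its acquisition setting")
})

test_that("normalization modes rescale each exposure series to a unit maximum", {
  d <- tibble::tibble(exposure_ms = 10, concentration = 10^-(1:3),
                      mean = c(8, 4, 2), sd = 0, n = 3)
  cur <- response_curve(d, tibble::tibble(exposure_ms = 10, blank_mean = 0,
                                          blank_sd = 0, blank_n = 3))
  mx <- normalize_curve(cur, "max")
  expect_equal(sort(mx$data$mean), c(0.25, 0.5, 1.0))
  mm <- normalize_curve(cur, "minmax")
  expect_equal(sort(mm$data$mean), c(0, 1 / 3, 1))

  # ordering within a series is preserved and max is exactly 1
  set.seed(8)
  rc <- random_curve(3, 6, seed = 8)
  nm <- normalize_curve(rc, "max")
  for (e in unique(nm$data$exposure_ms)) {
    raw <- rc$data$mean[rc$data$exposure_ms == e]
    nrm <- nm$data$mean[nm$data$exposure_ms == e]
    expect_equal(order(raw), order(nrm))
    expect_equal(max(nrm), 1.0)
  }

  flat <- response_curve(
    tibble::tibble(exposure_ms = 10, concentration = 10^-(1:3),
                   mean = 5, sd = 0, n = 3),
    tibble::tibble(exposure_ms = 10, blank_mean = 0, blank_sd = 0,
                   blank_n = 3))
  expect_error(normalize_curve(flat, "minmax"), "constant")
})

simple_curve <- function(means, blank_mean = 10, blank_sd = 1,
                         exposure = 10) {
  response_curve(
    tibble::tibble(exposure_ms = exposure,
                   concentration = 10^-seq(9, 8 + length(means)),
                   mean = means, sd = 0, n = 3),
    tibble::tibble(exposure_ms = exposure, blank_mean = blank_mean,
                   blank_sd = blank_sd, blank_n = 12))
}

test_that("the detection threshold is blank mean + k sd and drives the LOD", {
  cur <- simple_curve(c(14, 12))
  lod <- detection_limit(cur, k = 3)
  expect_equal(lod$thresholds$threshold, 13)
  expect_equal(lod$lod_molar, 1e-9)

  none <- detection_limit(simple_curve(c(11, 12)), k = 3)
  expect_true(is.na(none$lod_molar))
  expect_equal(none$status, "none detectable")

  # monotone closure: a detected concentration below an undetected one
  # does not set the LOD
  gap <- detection_limit(simple_curve(c(20, 12, 15)), k = 3)
  expect_equal(gap$lod_molar, 1e-9)
})

test_that("the LOD never increases when k decreases", {
  for (s in 1:6) {
    cur <- random_curve(3, 5, seed = 100 + s)
    l2 <- detection_limit(cur, k = 1)$lod_molar
    l4 <- detection_limit(cur, k = 4)$lod_molar
    if (!is.na(l4)) {
      expect_false(is.na(l2))
      expect_lte(l2, l4)
    }
  }
})

test_that("the LOD agrees with a brute-force enumeration oracle", {
  for (s in 1:10) {
    cur <- random_curve(sample(2:6, 1), sample(3:10, 1), seed = 200 + s)
    got <- detection_limit(cur, k = 3)$lod_molar
    want <- lod_oracle(cur, k = 3)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(want)) expect_equal(got, want)
  }
})

test_that("dynamic range spans detection to the saturation guard", {
  allsat <- simple_curve(c(255, 255, 255))
  expect_true(dynamic_range(allsat, 10)$empty)

  lin <- response_curve(
    tibble::tibble(exposure_ms = 10, concentration = 10^-(5:9),
                   mean = c(200, 20, 2, 0.2, 0.02), sd = 0, n = 3),
    tibble::tibble(exposure_ms = 10, blank_mean = 0.005, blank_sd = 0.001,
                   blank_n = 12))
  dr <- dynamic_range(lin, 10)
  expect_false(dr$empty)
  expect_equal(dr$decades, 4.0)    # 1e-5 through 1e-9, all quantifiable

  expect_error(dynamic_range(lin, 99), "not present")
})

test_that("longer exposures push the quantifiable floor downward", {
  exposures <- c(1, 10, 100)
  concs <- 10^-(5:10)
  d <- purrr::map_dfr(exposures, function(e)
    tibble::tibble(exposure_ms = e, concentration = concs,
                   mean = pmin(1e8 * concs * e, 255), sd = 0, n = 3))
  cur <- response_curve(d, tibble::tibble(exposure_ms = exposures,
                                          blank_mean = 0.5, blank_sd = 0.1,
                                          blank_n = 12))
  lows <- vapply(exposures, function(e) {
    dr <- dynamic_range(cur, e)
    if (dr$empty) Inf else dr$lowest
  }, numeric(1))
  expect_true(all(diff(lows) <= 0))
  expect_lt(lows[3], lows[1])
})

test_that("exposure recommendation maximizes coverage and breaks ties short", {
  one <- simple_curve(c(100, 50, 20))
  expect_equal(recommend_exposure(one, c(1e-10, 1e-8)), 10)

  two <- response_curve(
    tibble::tibble(exposure_ms = rep(c(1, 100), each = 2),
                   concentration = rep(c(1e-6, 1e-7), 2),
                   mean = c(5, 0.5, 200, 50), sd = 0, n = 3),
    tibble::tibble(exposure_ms = c(1, 100), blank_mean = 1, blank_sd = 0.5,
                   blank_n = 12))
  # at 1 ms only 1e-6 clears blank + 3 sd; at 100 ms both do, unsaturated
  expect_equal(recommend_exposure(two, c(1e-7, 1e-6)), 100)

  tie <- response_curve(
    tibble::tibble(exposure_ms = rep(c(5, 50), each = 2),
                   concentration = rep(c(1e-6, 1e-7), 2),
                   mean = c(100, 40, 120, 60), sd = 0, n = 3),
    tibble::tibble(exposure_ms = c(5, 50), blank_mean = 1, blank_sd = 0.5,
                   blank_n = 12))
  expect_equal(recommend_exposure(tie, c(1e-7, 1e-6)), 5)
})

test_that("4PL calibration recovers known parameters within 1%", {
  x <- seq(-6, 0, length.out = 9)      # log10 concentration
  truth <- list(bottom = 0, top = 1, lec50 = -3, slope = 1)
  y <- truth$bottom + (truth$top - truth$bottom) /
    (1 + 10^(truth$slope * (truth$lec50 - x)))
  cur <- response_curve(
    tibble::tibble(exposure_ms = 10, concentration = 10^x, mean = y,
                   sd = 0, n = 3),
    tibble::tibble(exposure_ms = 10, blank_mean = 0, blank_sd = 0,
                   blank_n = 3))
  fit <- sensor_calibration(cur)
  expect_equal(fit$bottom, 0, tolerance = 0.01)
  expect_equal(fit$top, 1, tolerance = 0.01)
  expect_equal(fit$ec50_molar, 1e-3, tolerance = 0.01)
  expect_equal(fit$slope, 1, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.9999)

  flat <- response_curve(
    tibble::tibble(exposure_ms = 10, concentration = 10^x, mean = 0.5,
                   sd = 0, n = 3),
    tibble::tibble(exposure_ms = 10, blank_mean = 0, blank_sd = 0,
                   blank_n = 3))
  expect_error(sensor_calibration(flat), "flat response")

  dec <- response_curve(
    tibble::tibble(exposure_ms = 10, concentration = 10^x, mean = rev(y),
                   sd = 0, n = 3),
    tibble::tibble(exposure_ms = 10, blank_mean = 0, blank_sd = 0,
                   blank_n = 3))
  expect_lt(sensor_calibration(dec)$slope, 0)
})

test_that("with shot noise, the median LOD is nonincreasing in exposure before saturation", {
  qe_g <- exp(-(520 - 540)^2 / (2 * 40^2))
  exposures <- c(1, 10, 100)
  concs <- 10^-(6:10)
  per_exposure_lod <- function(e, seed) {
    withr::with_seed(seed, {
      mu <- pmin(1e8 * concs * e * qe_g, 255)
      mean3 <- vapply(mu, function(m)
        mean(pmin(stats::rpois(3, m) + stats::rnorm(3, 0, 0.5), 255)),
        numeric(1))
      blanks <- stats::rnorm(12, 0.5, 0.5)
      cur <- response_curve(
        tibble::tibble(exposure_ms = e, concentration = concs,
                       mean = mean3, sd = 0, n = 3),
        tibble::tibble(exposure_ms = e, blank_mean = mean(blanks),
                       blank_sd = stats::sd(blanks), blank_n = 12))
      lod <- detection_limit(cur)$lod_molar
      if (is.na(lod)) Inf else lod
    })
  }
  meds <- vapply(seq_along(exposures), function(i)
    stats::median(vapply(1:20, function(r)
      per_exposure_lod(exposures[i], 1000 * i + r), numeric(1))),
    numeric(1))
  expect_true(all(diff(meds) <= 0))
})
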