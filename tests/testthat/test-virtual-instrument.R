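test_that("noise-free rendering is linear in exposure, clips at saturation, and hits black at zero signal", {
  lay <- plate_layout()
  cam <- camera_model(black_level = c(2, 3, 4))
  # zero concentration: counts equal the black level exactly
  dark_scene <- plate_scene(lay, 0, fluor_fitc(k = 1e6))
  fr0 <- render(dark_scene, blue_setting(10), cam)
  expect_equal(unique(as.numeric(fr0$pixels[, , 1])), 2)
  expect_equal(unique(as.numeric(fr0$pixels[, , 3])), 4)

  scene <- plate_scene(lay, 1e-6, fluor_fitc(k = 1e6, epsilon_l = 0))
  f1 <- render(scene, blue_setting(5), cam)
  f2 <- render(scene, blue_setting(10), cam)
  g <- detect_grid(f1, lay)
  v1 <- well_intensities(f1, g, background = "none")$value - 3
  v2 <- well_intensities(f2, g, background = "none")$value - 3
  expect_equal(v2, 2 * v1, tolerance = 1e-9)

  sat_scene <- plate_scene(lay, 1e-2, fluor_fitc(k = 1e10, epsilon_l = 0))
  fs <- render(sat_scene, blue_setting(1000), cam)
  ctr <- plate_centers(lay)
  expect_equal(fs$pixels[ctr$center_row[1] + 1, ctr$center_col[1] + 1, 2], 255)
})

test_that("rendering is reproducible given a seed and varies across seeds", {
  p <- preset_flatness_plate()
  a <- render(p$scene, p$setting, p$camera, p$led, seed = 5)
  b <- render(p$scene, p$setting, p$camera, p$led, seed = 5)
  c <- render(p$scene, p$setting, p$camera, p$led, seed = 6)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("raising drive level never decreases expected counts", {
  lay <- plate_layout()
  scene <- plate_scene(lay, 1e-7, fluor_fitc(k = 1e8))
  flt <- filter_model("bandpass", center_nm = 542, halfwidth_nm = 25)
  lo <- render(scene, acquisition_setting(10, "blue_460", 0.3, flt))
  hi <- render(scene, acquisition_setting(10, "blue_460", 0.8, flt))
  expect_true(all(hi$pixels - lo$pixels >= -1e-12))
})

test_that("long-pass signal is nonincreasing in cut-on for the same scene", {
  m <- preset_minerals()
  s1 <- acquisition_setting(10, "external_uv", 1,
                            filter_model("longpass", cuton_nm = 455))
  s2 <- acquisition_setting(10, "external_uv", 1,
                            filter_model("longpass", cuton_nm = 610))
  f1 <- render(m$scene, s1, m$camera, m$led)
  f2 <- render(m$scene, s2, m$camera, m$led)
  expect_true(all(f1$pixels - f2$pixels >= -1e-12))
})

test_that("unknown LED channel and invalid exposure are rejected", {
  expect_error(acquisition_setting(-5, "blue_460", 1), "exposure")
  s <- acquisition_setting(10, "blue_460", 1)
  s$led_channel <- "magenta_999"
  expect_error(render(plate_scene(plate_layout(), 1e-6, fluor_fitc()), s),
               "unknown LED channel")
})

test_that("dark frames follow the zero-clipped Gaussian model", {
  quiet <- camera_model(black_level = c(5, 5, 5))
  ds0 <- dark_stack(quiet, 2, 10, 10, seed = 1)
  expect_true(all(ds0$frames[[1]]$pixels == 5))

  noisy <- camera_model(black_level = c(0, 0, 0),
                        read_noise_sd = c(2, 2, 2))
  dsn <- dark_stack(noisy, 2, 50, 50, seed = 2)
  expect_true(all(dsn$frames[[1]]$pixels >= 0))
})

test_that("dark-stack moments match the closed-form clipped-normal moments", {
  mu <- -0.3; sigma <- 1.2
  cam <- camera_model(black_level = rep(mu, 3), read_noise_sd = rep(sigma, 3))
  st <- stack_mean_std(dark_stack(cam, 4, 300, 300, seed = 9))
  want <- clipped_normal_moments(mu, sigma)
  # Monte-Carlo tolerance: ~4 SE of the mean over 360k draws
  expect_true(all(abs(st$mean - want["mean"]) < 4 * sigma / sqrt(360000) + 0.01))
  expect_true(all(abs(st$sd - want["sd"]) < 0.02))
})

test_that("clipped-normal moments agree with a numerical-integration oracle", {
  for (p in list(c(-0.5, 1), c(0.2, 0.8), c(1.5, 2))) {
    mu <- p[1]; sigma <- p[2]
    m1 <- stats::integrate(function(x) x * dnorm(x, mu, sigma), 0, Inf,
                           rel.tol = 1e-10)$value
    m2 <- stats::integrate(function(x) x^2 * dnorm(x, mu, sigma), 0, Inf,
                           rel.tol = 1e-10)$value
    want <- c(m1, sqrt(m2 - m1^2))
    got <- clipped_normal_moments(mu, sigma)
    expect_equal(unname(got), want, tolerance = 1e-6)
  }
})

test_that("moment matching inverts the clipped-normal moments", {
  par <- match_clipped_normal(0.50, 0.84)
  back <- clipped_normal_moments(par["mu"], par["sigma"])
  expect_equal(unname(back), c(0.50, 0.84), tolerance = 1e-4)
})

test_that("the inner-filter factor is strictly decreasing and tends to 1", {
  cs <- 10^seq(-9, -2)
  v <- f_sat(cs, 22500)
  expect_true(all(diff(v) < 0))
  # series expansion at epsilon_l * c = 1e-6
  x <- 1e-6
  expect_equal(f_sat(x / 22500, 22500), 1 - x * log(10) / 2,
               tolerance = 1e-4)
  expect_lt(abs(f_sat(1e-12, 1) - 1), 1e-10)
})

test_that("render_sweep yields one frame per setting with increasing signal until saturation", {
  d <- preset_fitc_dilution()
  one <- render_sweep(d$scene, d$settings[1], quiet_camera(), d$led)
  expect_length(one, 1)

  lay <- plate_layout()
  scene <- plate_scene(lay, 1e-7, fluor_fitc(k = 1e7, epsilon_l = 0))
  sw <- render_sweep(scene, lapply(c(1, 10, 100), blue_setting),
                     quiet_camera(), led_model())
  g <- detect_grid(sw$frames[[3]], lay)
  means <- vapply(sw$frames, function(f)
    mean(well_intensities(f, g, background = "none")$value), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(means[3], 255)
})
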