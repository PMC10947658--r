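mineral_sweep <- function() {
  m <- preset_minerals()
  list(preset = m,
       stack = render_sweep(m$scene, m$settings, m$camera, m$led))
}

test_that("series building orders signals by cut-on and validates inputs", {
  m <- preset_minerals()
  one <- render_sweep(m$scene, m$settings[6], m$camera, m$led)
  ser <- build_series(one, m$regions["mineral1"])
  expect_equal(nrow(ser), 3)               # one cut-on x three channels
  expect_equal(unique(ser$cuton_nm), 530)

  dup <- image_stack(c(one$frames, one$frames))
  expect_error(build_series(dup, m$regions["mineral1"]), "duplicate")
})

test_that("an emitter below the shortest cut-on gives zero signal", {
  sc <- mineral_scene(list(list(label = "uv", row0 = 10, row1 = 40,
                                col0 = 10, col1 = 40,
                                emission = data.frame(lambda_nm = 420,
                                                      weight = 1),
                                rate = 15)))
  pre <- preset_minerals()
  st <- render_sweep(sc, pre$settings, quiet_camera(), pre$led)
  ser <- build_series(st, list(uv = region_box(10, 40, 10, 40, "uv")))
  expect_true(all(ser$signal == 0))
})

test_that("a 550 nm emitter peaks in the green channel", {
  sw <- mineral_sweep()
  ser <- build_series(sw$stack, sw$preset$regions)
  open_filter <- dplyr::filter(ser, .data$region == "mineral4",
                               .data$cuton_nm == 435)
  expect_equal(open_filter$channel[which.max(open_filter$signal)], "G")
})

test_that("channel response is nonincreasing with no flags on noise-free input", {
  sw <- mineral_sweep()
  ser <- build_series(sw$stack, sw$preset$regions)
  for (ch in c("R", "G", "B", "gray")) {
    cr <- channel_response(ser, ch, region = "mineral6")
    expect_true(all(diff(cr$signal) <= 1e-9))
    expect_equal(sum(cr$adjusted), 0)
  }
})

test_that("an upward noise blip is flattened by isotonic repair and flagged", {
  ser <- tibble::tibble(region = "x", channel = "G",
                        cuton_nm = c(435, 455, 475),
                        signal = c(10, 11, 5))
  class(ser) <- c("spectral_series", class(ser))
  cr <- channel_response(ser, "G")
  # pool-adjacent-violators by hand: nonincreasing fit of (10, 11, 5)
  expect_equal(cr$signal, c(10.5, 10.5, 5))
  expect_equal(cr$adjusted, c(TRUE, TRUE, FALSE))
})

test_that("the combined response equals luma-weighted channel responses", {
  sw <- mineral_sweep()
  ser <- build_series(sw$stack, sw$preset$regions)
  r <- channel_response(ser, "R", region = "mineral2")$raw
  g <- channel_response(ser, "G", region = "mineral2")$raw
  b <- channel_response(ser, "B", region = "mineral2")$raw
  gray <- channel_response(ser, "gray", region = "mineral2")$raw
  expect_equal(gray, 0.299 * r + 0.587 * g + 0.114 * b, tolerance = 1e-12)
})

test_that("band reconstruction telescopes and conserves the total signal", {
  sw <- mineral_sweep()
  ser <- build_series(sw$stack, sw$preset$regions)
  for (reg in c("mineral1", "mineral5", "mineral9")) {
    cr <- channel_response(ser, "gray", region = reg)
    bs <- band_reconstruct(cr)
    expect_equal(sum(bs$energy), cr$signal[1], tolerance = 1e-9)
  }
})

test_that("band reconstruction localizes line emitters", {
  line_series <- function(cutons, signals) {
    tibble::tibble(cuton_nm = cutons, signal = signals)
  }
  # 550 nm line with cut-ons 530 / 570: all energy in [530, 570)
  bs <- band_reconstruct(line_series(c(530, 570), c(12, 0)))
  expect_equal(bs$energy, c(12, 0))
  # 700 nm emitter with cut-ons up to 695: everything in the open band
  bs2 <- band_reconstruct(line_series(c(645, 695), c(9, 9)))
  expect_equal(bs2$energy, c(0, 9))
  expect_equal(bs2$lambda_hi[2], Inf)

  expect_error(band_reconstruct(line_series(c(570, 530), c(1, 2))), "sorted")
})

test_that("the anthocyanin index is a log excitation ratio", {
  a <- const_frame(c(40, 40, 40), H = 6, W = 6)
  expect_equal(anthocyanin_index(a, a)$mean, 0)

  b <- const_frame(c(80, 80, 80), H = 6, W = 6)
  ai <- anthocyanin_index(a, b)
  expect_equal(ai$mean, log(2), tolerance = 0.01)   # eps = 0.5 << 40

  # antisymmetry far from the epsilon guard
  expect_equal(anthocyanin_index(a, b)$mean, -anthocyanin_index(b, a)$mean,
               tolerance = 1e-12)
  expect_error(anthocyanin_index(a, const_frame(c(1, 1, 1), H = 3, W = 3)),
               "shape")
})

test_that("simulated leaf decay raises the index monotonically over days", {
  days <- 0:6
  red <- const_frame(c(90, 90, 90), H = 8, W = 8)
  ais <- vapply(days, function(d) {
    green <- const_frame(rep(100 * exp(-0.35 * d), 3), H = 8, W = 8)
    anthocyanin_index(green, red)$mean
  }, numeric(1))
  expect_true(all(diff(ais) > 0))
})
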