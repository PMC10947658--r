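make_plate <- function(conc = 1e-6, k = 2e7, vignetting = 0, seed = 1,
                       camera = quiet_camera()) {
  lay <- plate_layout()
  scene <- plate_scene(lay, conc, fluor_fitc(k = k, epsilon_l = 0),
                       vignetting = vignetting)
  list(frame = render(scene, blue_setting(10), camera, seed = seed),
       layout = lay)
}

test_that("grid detection refines all 96 wells to within a pixel", {
  p <- make_plate()
  g <- detect_grid(p$frame, p$layout)
  expect_equal(nrow(g), 96)
  expect_equal(g$label[c(1, 12, 85, 96)], c("A1", "A12", "H1", "H12"))
  truth <- plate_centers(p$layout)
  expect_lt(max(abs(g$center_row - truth$center_row)), 1)
  expect_lt(max(abs(g$center_col - truth$center_col)), 1)
})

test_that("grid detection works without a layout via lattice autocorrelation", {
  p <- make_plate()
  g <- detect_grid(p$frame)
  truth <- plate_centers(p$layout)
  expect_equal(nrow(g), 96)
  expect_lt(max(abs(g$center_row - truth$center_row)), 1)
  expect_lt(max(abs(g$center_col - truth$center_col)), 1)
})

test_that("a blank frame yields no grid", {
  blank <- const_frame(c(3, 3, 3), H = 360, W = 520)
  expect_error(detect_grid(blank, plate_layout()), "grid not found")
})

test_that("well intensities recover uniform and per-well ground truth", {
  uf <- const_frame(c(40, 40, 40), H = 360, W = 520)
  lay <- plate_layout()
  g <- structure(plate_centers(lay), layout = lay,
                 class = c("well_grid", "tbl_df", "tbl", "data.frame"))
  wi <- well_intensities(uf, g, background = "none")
  expect_true(all(wi$value == 40))
  wa <- well_intensities(uf, g, background = "annulus")
  expect_true(all(wa$value == 0))

  # per-well signal ground truth from the forward model, noise off
  lay2 <- plate_layout()
  set.seed(9)
  conc <- matrix(runif(96, 0.5, 2) * 1e-6, 8, 12)
  scene <- plate_scene(lay2, conc, fluor_fitc(k = 8e6, epsilon_l = 0))
  fr <- render(scene, blue_setting(10), quiet_camera())
  gg <- detect_grid(fr, lay2)
  vals <- well_intensities(fr, gg, background = "none")$value
  # G-channel QE at the 520 nm emission line; the 542 +/- 25 bandpass passes it
  qe_g <- exp(-(520 - 540)^2 / (2 * 40^2))
  expected <- as.numeric(t(conc)) * 8e6 * 10 * qe_g
  expect_true(all(abs(vals - expected) / expected < 0.01))
})

test_that("percent deviation matches hand arithmetic and sums to zero", {
  expect_equal(attr(percent_deviation(rep(7, 12)), "max_abs_pct"), 0)

  v <- c(rep(100, 95), 103)
  pd <- percent_deviation(v)
  expect_equal(attr(pd, "max_abs_pct"), 100 * (103 - mean(v)) / mean(v),
               tolerance = 1e-12)
  expect_equal(attr(pd, "max_abs_pct"), 2.968, tolerance = 1e-3)

  for (s in 1:5) {
    set.seed(s)
    pd <- percent_deviation(runif(96, 50, 150))
    expect_lt(abs(sum(pd$deviation_pct)), 1e-9)
  }
  expect_error(percent_deviation(c(1)), "at least 2")
  expect_error(percent_deviation(c(-1, 1)), "mean must be > 0")
})

test_that("well intensities are equivariant to plate translation", {
  lay1 <- plate_layout(origin_px = c(40, 40))
  lay2 <- plate_layout(origin_px = c(45, 43))
  set.seed(10)
  conc <- matrix(runif(96, 0.5, 2) * 1e-6, 8, 12)
  f1 <- render(plate_scene(lay1, conc, fluor_fitc(k = 8e6)), blue_setting(10),
               quiet_camera())
  f2 <- render(plate_scene(lay2, conc, fluor_fitc(k = 8e6)), blue_setting(10),
               quiet_camera())
  v1 <- well_intensities(f1, detect_grid(f1, lay1), background = "none")$value
  v2 <- well_intensities(f2, detect_grid(f2, lay2), background = "none")$value
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("flat-field correction with the true field removes vignetting", {
  # constant field: identity
  fr <- make_plate()$frame
  same <- flat_field_correct(fr, matrix(2, 360, 520))
  expect_equal(same$pixels, fr$pixels, tolerance = 1e-12)

  # noise off: correcting with the true illumination nulls the deviation
  p <- make_plate(vignetting = 0.02)
  field <- radial_vignette(c(360, 520), 0.02)
  corr <- flat_field_correct(p$frame, field)
  g <- detect_grid(corr, p$layout)
  dev <- percent_deviation(well_intensities(corr, g, background = "none"))
  expect_lt(attr(dev, "max_abs_pct"), 0.1)

  expect_error(flat_field_correct(fr, matrix(0, 360, 520)), "positive")
})

test_that("true-field correction never increases the noise-free flatness deviation", {
  p <- make_plate(vignetting = 0.02)
  g <- detect_grid(p$frame, p$layout)
  before <- attr(percent_deviation(well_intensities(p$frame, g,
                                                    background = "none")),
                 "max_abs_pct")
  corr <- flat_field_correct(p$frame, radial_vignette(c(360, 520), 0.02))
  after <- attr(percent_deviation(well_intensities(corr, g,
                                                   background = "none")),
                "max_abs_pct")
  expect_lte(after, before)
  expect_gt(before, 0.5)
})
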