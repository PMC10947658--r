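# Shared fixtures and independent oracles, built in code at test time.

# frame with constant per-channel values
const_frame <- function(vals, H = 4, W = 5, bit_depth = 8) {
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- vals[ch]
  image_frame(px, bit_depth = bit_depth)
}

# noise-free camera / setting used across rendering tests
quiet_camera <- function(bit_depth = 8) camera_model(bit_depth = bit_depth)

blue_setting <- function(exposure_ms = 10, cuton = NULL) {
  flt <- if (is.null(cuton)) filter_model("bandpass", center_nm = 542,
                                          halfwidth_nm = 25)
         else filter_model("longpass", cuton_nm = cuton)
  acquisition_setting(exposure_ms, "blue_460", 1, flt)
}

# independent LOD oracle: literal enumeration of the definition over the
# (exposure x concentration) grid, no shared code with detection_limit()
lod_oracle <- function(curve, k = 3) {
  blanks <- curve$blanks
  concs <- sort(unique(curve$data$concentration), decreasing = TRUE)
  detected <- logical(length(concs))
  for (ci in seq_along(concs)) {
    for (ei in seq_len(nrow(blanks))) {
      thr <- blanks$blank_mean[ei] + k * blanks$blank_sd[ei]
      row <- curve$data[curve$data$concentration == concs[ci] &
                          curve$data$exposure_ms == blanks$exposure_ms[ei], ]
      if (nrow(row) == 1 && row$mean > thr) detected[ci] <- TRUE
    }
  }
  lod <- NA_real_
  for (ci in seq_along(concs)) {
    if (!detected[ci]) break
    lod <- concs[ci]
  }
  lod
}

# random summary-level response curve on an n_exp x n_conc grid
random_curve <- function(n_exp, n_conc, seed) {
  withr::with_seed(seed, {
    exps <- sort(sample(c(1, 3, 10, 30, 100, 300, 1000), n_exp))
    concs <- 10^-seq(3, 3 + n_conc - 1)
    d <- expand.grid(exposure_ms = exps, concentration = concs)
    d$mean <- runif(nrow(d), 0, 30)
    d$sd <- runif(nrow(d), 0, 2)
    d$n <- 3
    blanks <- data.frame(exposure_ms = exps,
                         blank_mean = runif(n_exp, 0, 2),
                         blank_sd = runif(n_exp, 0.1, 1), blank_n = 12)
    response_curve(d, blanks)
  })
}
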