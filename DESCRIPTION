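Package: fluorbox
Title: Virtual Fluorescence Imaging Box and Quantification Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physically parameterized virtual fluorescence imaging
    instrument (LED excitation, ideal step filters, RGB camera with black
    level, read and shot noise) together with the calibration and
    quantification procedures used to characterize such an instrument:
    dark-frame black-level statistics, color-chart accuracy, lens
    distortion and 1951 USAF resolution analysis, 96-well plate grid
    detection, flatness and flat-field correction, exposure-sweep
    dose-response curves with limit-of-detection and dynamic-range
    analysis, four-parameter logistic sensor calibration, gel lane
    densitometry, long-pass filter-series spectral reconstruction, an
    anthocyanin excitation-ratio index, and time-lapse specimen growth
    tracking. Analysis functions return tibbles; fitted objects provide
    broom-style tidy() and glance() methods and ggplot2 autoplot()s.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    minpack.lm,
    pracma,
    withr,
    tools,
    EBImage,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
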