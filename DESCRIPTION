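Package: actipatterns
Title: Regression and Multivariate Pattern Analysis of Accelerometer
    Intensity Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Relates the accelerometer-derived physical-activity intensity
    spectrum to a composite cardiometabolic health score, comparing multiple
    linear regression and partial least squares (PLS) based multivariate
    pattern analysis on both raw and log-ratio transformed data. Provides
    epoch-level accelerometry processing (non-wear detection, wear-time
    validity, counts-per-minute intensity binning), a sex- and age-adjusted
    composite cardiometabolic risk score, compositional machinery (closure,
    centred log-ratios, pivot-coordinate isometric log-ratios with the
    all-first permutation scheme), PLS regression with Monte Carlo
    cross-validation, target projection and selectivity ratios with
    resampling confidence intervals, closure-distortion diagnostics, and a
    synthetic data generator that reproduces the closed, multicollinear
    structure of intensity-spectrum data so the whole pipeline is testable
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tibble,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
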