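Package: continf
Title: Threshold-Based Statistical Inference for Registered 1-D Continua
Version: 0.1.0
Authors@R:
    person("continf", "developers", email = "continf@example.org", role = c("aut", "cre"))
Description: Node-wise t-statistic continua (SPM{t}) for registered
    one-dimensional waveform data (gait cycles, ground reaction forces and
    other 0-100% registered biomechanical signals), with four domain-wide
    critical thresholds: uncorrected, Bonferroni, random field theory (RFT)
    based on the expected Euler characteristic of smooth t-fields, and
    Benjamini-Hochberg false discovery rate (FDR). Includes a validated
    smooth 1-D Gaussian field generator parameterized by full-width-at-
    half-maximum (FWHM), a residual-based FWHM estimator, and a Monte Carlo
    harness that maps threshold convergence and divergence across sample
    size, smoothness, and signal geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
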