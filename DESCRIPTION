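Package: thznitro
Title: Terahertz Spectral Band Selection and Calibration for Leaf Nitrogen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A chemometrics pipeline for estimating leaf nitrogen content
    from terahertz power spectra. Provides Savitzky-Golay smoothing,
    Kennard-Stone and random calibration/prediction partitioning, a PLS1
    regression engine with cross-validation, three characteristic
    frequency-band selectors (uninformative variable elimination, stability
    competitive adaptive reweighted sampling, and interval PLS), two
    calibration models (an exact-design radial basis function network and a
    small backpropagation network), a seeded synthetic spectra generator
    with planted nitrogen-informative absorption bands for benchmarking,
    and an end-to-end pipeline orchestrator with reproducible sub-seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
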