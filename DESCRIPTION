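Package: isasync
Title: Phase Synchronization Between Infra-Slow EEG and Electrodermal Arousal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for correlations between autonomic arousal and
    infra-slow brain activity: extracts instantaneous phases of infra-slow
    (0.01-0.1 Hz) EEG and galvanic-skin-response oscillations (detrending,
    downsampling, spherical-spline surface Laplacian, zero-phase FIR
    filtering, Hilbert transform), quantifies their phase synchronization
    index with time-shuffle surrogate permutation tests, measures coupling
    between synchronization strength and mean phase difference via a binned
    Kullback-Leibler statistic, maps grand-mean phase-difference topographies
    against the principal gradient of channel functional connectivity
    (diffusion-map embedding), and compares meditator and novice groups with
    rank-sum tests, FDR correction and effect sizes. Includes a synthetic
    cohort generator with von Mises phase-jitter ground truth, EDF/BDF
    reading and EDF writing, and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
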