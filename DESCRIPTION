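Package: bromeg
Title: Blink-Related Oscillation Analysis for MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for characterizing blink-related
    oscillations (BROs) in magnetoencephalography. Includes a spherical
    (Sarvas) forward model for axial gradiometer arrays, a synthetic
    MEG+vEOG recording generator with planted ground truth, template-matching
    blink detection with morphology features and split-half reliability,
    ICA-based ocular artifact removal with blink-to-baseline power-ratio
    validation, delta-band global field power and Morlet time-frequency
    statistics at the sensor level, minimum-norm source localization with
    max-statistic permutation FWE control, and virtual-electrode time-course
    analysis with cluster-based permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ica,
    rhdf5,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
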