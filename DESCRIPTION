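Package: polcoloc
Title: Single-Cell Polarity and Colocalisation Quantification for
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("polcoloc", "developers", email = "polcoloc@example.org",
           role = c("aut", "cre"))
Description: Quantifies intracellular compartment polarisation and
    colocalisation in single-cell fluorescence image crops. Provides a
    difference-of-Gaussians bandpass at physical (micrometre) scales, Otsu
    thresholding, connected-component cluster labeling, intensity-weighted
    centroid and asymmetry statistics, cluster half-width, per-spot features,
    Costes automatic threshold colocalisation with Pearson and Manders
    coefficients, a synthetic single-cell image generator with planted ground
    truth, a minimal multi-page TIFF reader/writer, and a batch command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
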