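Package: ecgtda
Title: Topological Quality Assessment of Ambulatory ECG Signals
Version: 0.1.0
Authors@R:
    person("ECG", "TDA Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assesses the quality of 10-second ambulatory electrocardiogram
    (ECG) segments with persistent homology. Segments are delay-embedded into
    point clouds by a sliding-window map, summarised by Vietoris-Rips (H0/H1)
    or sublevel-set (H0) persistence, rendered as deterministic barcode or
    diagram raster images, and classified as acceptable or unacceptable under
    stratified k-fold cross-validation. Includes a synthetic data factory that
    emulates clean P-QRS-T waveforms and four contaminant classes (baseline
    wander, electrode motion, muscle artifact, white Gaussian noise) mixed at
    a controlled signal-to-noise ratio, plus readers and writers for WFDB
    format-16 and columnar CSV records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
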