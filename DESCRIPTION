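Package: ramanlcw
Title: Label-Free Raman Chemical Imaging of Plant Cell-Wall Lignocellulose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative chemical imaging of cellulose,
    hemicellulose and lignin in plant tissue from hyperspectral Raman map
    scans. Implements the full analysis chain: background segmentation,
    cosmic-ray despiking, adaptive iteratively reweighted penalized
    least-squares (airPLS) baseline correction, PCA denoising, area and
    maximum normalization, level-8 discrete wavelet single-branch feature
    extraction for fluorescence suppression, PCA clustering with
    loading-weight band analysis, LDA/KNN classification of treated versus
    untreated spectra, fully constrained least-squares (FCLS) spectral
    unmixing against lignocellulosic reference standards, concentration
    calibration, and rendering of subcellular concentration images and
    histograms. Includes a synthetic-scene generator with known ground
    truth for validating abundance recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
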