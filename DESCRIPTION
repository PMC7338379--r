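Package: spheroidscreen
Title: Image-Based Viability Classification for 3D Spheroid Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for an automated drug-efficacy readout on hanging-drop
    cell spheroids. Generates class-conditional synthetic brightfield
    micrographs of spheroids spanning the phenotype spectrum from cohesive,
    sharp-edged aggregates to fragmented cell masses; simulates Annexin-V
    flow-cytometry event tables and gates them into live/apoptotic fractions
    to derive three-category viability labels (unaffected, mildly affected,
    affected); declares, shape-checks and parameter-counts a small
    convolutional network for three-class spheroid classification and trains
    it from scratch with real-time label-preserving data augmentation under a
    stratified 80/20 split with five-fold cross-validation; and provides
    classical morphometry (projected-area volume, boundary edge contrast,
    solidity) as an interpretable baseline. Includes per-class
    precision/recall/F1 reporting and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
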