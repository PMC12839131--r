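Package: spheromet
Title: Label-Free Multiparametric Analysis of 3D Spheroid Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for brightfield, label-free drug screening on
    3D tumour spheroids. Segments one spheroid per frame and extracts
    CellProfiler-compatible morphometric features (area, perimeter, form
    factor, compactness, solidity, median radius, granularity spectrum),
    applies assay-specific triplicate quality control (Dixon Q-test
    replacement with a monotonicity guard for morphometry; coefficient-of-
    variation rules with plate-validity logic for fluorescence), collapses
    the features into a single PCA-weighted composite response metric, fits
    four-parameter logistic dose-response curves with explicit IC50
    censoring, and validates image-derived potencies against proliferation
    readouts by Pearson and Spearman concordance. A synthetic-data module
    generates spheroid images and dose-structured feature tables with known
    ground truth so every stage is testable without raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    grDevices,
    utils,
    minpack.lm,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
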