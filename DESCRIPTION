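Package: famet
Title: Single-Cell Focal Adhesion Metrology and Confinement-State Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An automated single-cell bioimage analysis workflow for
    fluorescence microscopy of adherent cells stained for actin (red),
    vinculin-rich focal adhesions (green), and the nucleus (blue).
    Segments the cell body, nucleus and focal adhesions from calibrated
    multi-channel images (maximum projection, CLAHE, non-local-means
    denoising, Otsu thresholding, conditional erosion, hole filling, and
    area-based triage of adhesions into cytosolic background, nascent and
    mature bins); computes moment-invariant shape descriptors
    (ellipticity, rectangularity, solidity), focal-adhesion size and
    aspect-ratio statistics, and spatial-distribution metrics (the
    perinuclear E-function slope and the nearest-neighbour G-function);
    and classifies single-cell confinement states with a cross-validated
    linear support vector machine, including univariate ANOVA-F feature
    ranking and coefficient-of-variation heterogeneity reporting. A
    synthetic-scene generator with full ground truth emulates four
    confinement-state archetypes so the entire pipeline is testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    e1071,
    MASS,
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
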