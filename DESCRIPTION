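Package: maxillomorph
Title: Digital Maxillary Morphometry for Two-Segment Reconstruction Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for region-wise digital analysis of maxillary surface
    morphology against a common reference skull, aimed at planning
    semi-standardized two-segment free-fibula reconstructions of
    hemimaxillectomy defects. Provides bone segmentation of CT-like volumes by
    Hounsfield-unit thresholding with iso-surface extraction; rigid mesh
    registration by three-point landmark (Kabsch) alignment refined with a
    radius-trimmed iterative closest point fit; signed surface-deviation fields
    within a validity window and the seven region summary parameters (Dmax,
    Dmin, Dmean, DSD, AVD, ID, IAD) with false-colour mesh export; construction
    of the reconstruction landmarks (A, IOr/IOl, J, O, M, X), segment lengths
    AX and MX and the three-point angle between them, with side pooling into a
    mean-value cutting-guide template; cohort statistics (Tukey IQR outliers,
    Welch t, one-way ANOVA, chi-square, Pearson correlation, univariate k-means
    with elbow selection); and a synthetic skull-phantom generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    yaml,
    optparse
Config/testthat/edition: 3
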