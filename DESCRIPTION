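Package: sijmri
Title: Sacroiliac Joint Delineation and Multi-Reader Lesion Classification for MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-stage analysis of coronal sacroiliac-joint (SIJ) MRI. Stage one
    delineates the left and right SIJs as open contours by regressing per-pixel
    unit vector fields together with Gaussian source/sink endpoint heatmaps and
    walking from source to sink along the field. Stage two rotation-aligns the
    volume, extracts minimum bounding-box regions of interest, and classifies
    five binary lesion types (bone marrow oedema, fatty lesions, erosions,
    sclerosis, ankylosis) from paired T1-weighted and STIR crops with a shared
    convolutional encoder and per-task linear heads. Training uses a
    hierarchical multi-reader scheme in which rank-1 annotator matrices arranged
    in a consensus tree model per-reader and per-session label noise, with a
    trace-regularised cross-entropy loss. A synthetic-data module generates
    contour-annotated slices, drifting volumes, planted-lesion ROI pairs and
    multi-reader labels with known flip rates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    RNifti,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
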