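Package: lvssm
Title: Left-Ventricle Statistical Shape Modelling and Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical shape analysis of the left ventricle for predicting
    one-year post-TAVR LVMI regression. Provides segmentation-label clean-up
    (morphological closing, ball median filtering, largest-component
    isolation), watertight iso-surface extraction with Laplacian smoothing,
    uniform farthest-point down-sampling, fixed-scale iterative closest
    point alignment with bijective point correspondence, mean-shape and
    deviation-vector construction, supervised (PLS1/NIPALS) and unsupervised
    (PCA) shape encoding, VIP-based anatomical localization of outcome
    signal, linear support-vector regression of the outcome, and a
    ground-truthed parametric synthetic LV cohort generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
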