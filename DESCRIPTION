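Package: gaitsym
Title: Bilateral Running-Gait Asymmetry Analysis from Ground Reaction Forces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing bilateral asymmetry of running gait from
    three-axis ground reaction force (GRF) waveforms: stance-phase detection
    and 101-node body-weight normalisation, the Nigg Symmetry Function with
    asymmetric-interval extraction, one-dimensional statistical parametric
    mapping (paired t-fields with random-field-theory thresholds and
    sign-flip permutation cluster p-values), and soft-margin kernel SVM
    classification of left-versus-right and pre-versus-post-fatigue gait
    (SMO dual solver, C/G grid search, stratified five-fold cross-validation,
    ACC/SEN/SEP evaluation with an exact confusion-matrix consistency
    solver). Includes a seeded synthetic bilateral GRF generator with
    injectable limb-dominance and fatigue effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
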