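Package: ramanblast
Title: Predicting Extended Embryo Culture Outcomes from Raman Spectra of
    Spent Day 3 Culture Medium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete, reproducible pipeline for classifying extended
    embryo culture outcomes (morphologically good blastocyst, non-good
    blastocyst, clinically non-useful embryo) from Raman spectra of spent
    Day 3 culture medium. Includes a hierarchical synthetic-spectrum
    generator with the eighteen core peaks and their group-wise intensity
    patterns, a preprocessing pipeline (quality control, cosmic-ray
    despiking, resampling, asymmetric least squares baseline correction,
    Savitzky-Golay smoothing, area normalization), per-peak group
    statistics and pattern classification, dimensionality-reduction views
    (t-SNE, latent Dirichlet allocation topics, OPLS-DA), a twelve-family
    classifier registry with SMOTE class balancing and sample-level
    cross-validation, and a stacked ensemble with mode-based per-sample
    vote aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    signal,
    MASS,
    nnet,
    e1071,
    ranger,
    xgboost,
    caret,
    pROC,
    yaml,
    jsonlite,
    withr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
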