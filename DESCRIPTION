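Package: mammocad
Title: Block-Statistical Mammogram Classification Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided detection (CAD) pipeline for mediolateral-oblique
    (MLO) mammograms: contrast-limited adaptive histogram equalization,
    orientation normalization, radiopaque-artifact suppression, pectoral-muscle
    removal by seeded region growing, block-wise statistical feature extraction
    (entropy, mean, variance, standard deviation, range, minimum, maximum, RMS
    over 16x16 blocks), rotation/flip dataset augmentation, individual
    classifiers (k-nearest neighbours, gain-ratio decision trees, random trees,
    random forests), ensemble systems (bagging, AdaBoost.M1, averaging fusion),
    wrapper feature selection (best-first and random search), and stratified
    (nested) cross-validated evaluation with confusion-matrix metrics and ROC
    AUC. Ships a synthetic MLO phantom generator with ground-truth masks so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
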