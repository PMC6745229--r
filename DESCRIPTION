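Package: lungtexsel
Title: Texture-Based Lung CT Nodule Classification with Chaotic
    Crow-Search Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a classical lung-CT
    computer-aided-diagnosis pipeline: adaptive-median impulse-noise
    filtering and morphological lung-field segmentation, gray-level
    co-occurrence matrix (GLCM) Haralick texture features, wrapper
    feature selection by a chaotic (sine-map) binary crow-search
    metaheuristic, and a probabilistic neural network (Bayes-Parzen)
    classifier evaluated with stratified 10-fold cross-validation.
    Includes a seeded phantom generator producing CT-like slices with
    ground-truth lung and nodule masks, and labelled feature tables
    with a planted informative subset, so that every stage is testable
    without access to clinical imaging archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    caret,
    jsonlite,
    png,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
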