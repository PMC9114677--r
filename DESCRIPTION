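Package: bitfusion
Title: Bit-Fusion Ensemble Classification and Classical Combiner Baselines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trainable fusion of base-classifier soft class supports by
    weighted threshold binarization: per-instance support matrices are
    weighted, thresholded into bit patterns, trained with a multiplicative
    perceptron-style error update, and classified by per-class bit counts.
    Includes the five standard base classifiers (naive Bayes, CART, RBF-SVM,
    k-NN, MLP), classical combiner baselines (majority voting, distribution
    summation, Dempster-Shafer, Borda count, highest rank, entropy and
    accuracy weighting), min-max/PCA preprocessing with leakage-safe fitting,
    stratified k-fold cross-validation with accuracy-gain statistics, and
    seeded synthetic generators for Gaussian feature tables and raw support
    tensors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
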