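Package: koivision
Title: Hybrid Convolutional-Network and Kernel-SVM Classification of Koi Varieties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-grained classification of the thirteen ornamental koi
    varieties with a hybrid classifier: an AlexNet-derived convolutional
    network in which local response normalization is replaced by batch
    normalization and eight identity-skip residual blocks deepen the feature
    extractor, whose softmax decision is replaced at prediction time by a
    kernel support vector machine fitted on fully-connected-layer features.
    Ships a procedural generator of thirteen visually distinguishable synthetic
    fish-pattern classes so the whole pipeline is testable without the original
    photographs, the six-operator augmentation and class-balancing scheme,
    stratified manifest handling, a from-scratch SMO dual solver with
    one-vs-one multiclass voting, macro-averaged evaluation metrics, and
    Grad-CAM introspection of the trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    generics,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab
Config/testthat/edition: 3
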