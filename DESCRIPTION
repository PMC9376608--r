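Package: ssmlr
Title: Self-Supervised Multimodal Learning for Pre-Speech EEG and Facial
    Action Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts upcoming fluent versus stuttered speech from the
    1,500 ms speech-preparation window using paired EEG epochs and facial
    action-unit (FACS AU) intensity time series. Implements self-supervised
    pretext training (paradigm classification on EEG; signal-transformation
    and window identification on AU data; cross-modal KL embedding
    alignment), compact convolutional encoders with a weighted-ensemble
    downstream classifier, DeepLIFT-style multimodal Shapley explanations
    with population-matched references, and ANOVA of attribution dynamics
    over face regions, electrode groups, and time zones. Includes a
    synthetic multimodal trial generator with planted, recoverable class
    structure and a Monte-Carlo Bayes-optimal reference oracle so the full
    pipeline is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    rhdf5,
    e1071
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
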