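Package: painfex
Title: Feature Extraction Comparison for Physiological Pain Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fixed evaluation harness for comparing feature extraction
    methods for heat-pain recognition from electrodermal activity (EDA).
    Includes a synthetic heat-pain study simulator with objective
    (stimulus temperature) and subjective (CoVAS rating) labels,
    stimulus-aligned segmentation with per-window min-max normalisation,
    tonic/phasic EDA decomposition with skin conductance response (SCR)
    detection and a 38-dimensional hand-crafted feature vector, four
    small neural feature extractors (MLP, CNN, ConvLSTM, convolutional
    autoencoder) trained by a built-in network engine, and a shared
    random-forest classifier evaluated by repeated leave-one-subject-out
    cross-validation with accuracy, macro-F1 and paired significance
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
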