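Package: birdnmf
Title: NMF-Based Acoustic Front-Ends for Bird Species Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Feature extraction and classification pipeline for acoustic
    bird species classification. Implements Kullback-Leibler non-negative
    matrix factorization (NMF) with multiplicative updates, unsupervised
    learning of an auditory filter bank from bird sound spectrograms
    (NMF_CC cepstral features), supervised per-species spectral basis
    models with activation-derived features (H_CC and the maximum-gain
    term G_NMF), syllable segmentation, temporal feature integration
    (mean, standard deviation, skewness per syllable), and an SVM-based
    evaluation harness with per-recording majority voting and stratified
    K-fold cross-validation. A synthetic vocalization generator provides
    labeled recordings with known ground truth for verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
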