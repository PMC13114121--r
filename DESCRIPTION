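Package: priorvae
Title: Prior-Conditioned Variational Autoencoder for Microbiome
    Response Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts binary immunotherapy response from gene-level
    (RPKM) microbial abundance profiles with a variational autoencoder
    whose latent space is conditioned on a fixed matrix of protein
    embeddings through multi-head attention. Includes mutual-information
    feature screening, stratified five-fold training and evaluation
    (accuracy, AUC, AUPR, bootstrap confidence intervals), an L1
    logistic baseline, cross-cohort transfer evaluation, integrated-
    gradients attribution with taxon-level aggregation, deterministic
    reference-set construction rules with RPKM normalization, and a
    synthetic cohort generator for end-to-end testing without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    pROC,
    optparse,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
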