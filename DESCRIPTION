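Package: mixehr
Title: Multi-View Topic Modelling of Heterogeneous EHR Data with
    Non-Random Lab Missingness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a multi-view Bayesian topic model to heterogeneous discrete
    electronic health record (EHR) data: counts of categorical features over
    several data types (notes words, diagnosis codes, prescriptions, ...)
    together with categorical lab results whose observation indicator depends
    on the latent disease topic (non-missing-at-random). Inference is by
    collapsed variational Bayes with a zero-order approximation (CVB0), in
    batch and stochastic (minibatch) variants, with empirical-Bayes
    fixed-point updates of all Dirichlet/Beta hyperparameters. Includes
    held-out predictive likelihood for choosing the number of topics, fold-in
    inference for new patients, k-nearest-neighbour EHR code prediction and
    lab-result imputation on the topic embedding, topic-embedding comorbidity
    correlation networks with permutation significance, a generative
    simulator for synthetic corpora, and loop-literal reference oracles used
    by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pROC,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
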