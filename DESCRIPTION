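Package: mtsgp
Title: Multi-Trait Sparse Genomic Prediction and Sparse Selection Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Sparse genomic prediction for single- and multi-trait/environment
    settings. Provides covariance-form Elastic-Net (coordinate descent) and
    LARS/LASSO-path solvers that operate on sufficient statistics, genomic
    relationship matrix construction, single-component REML/ML variance
    estimation with GBLUP, sparse selection indices, Kronecker-structured
    multi-trait sparse genomic prediction, CV2 training-testing partitioning,
    k-fold cross-validation for penalty selection, and synthetic-data
    generators for end-to-end testing. Result objects carry broom-style
    tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    glmnet,
    withr
Config/testthat/edition: 3
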