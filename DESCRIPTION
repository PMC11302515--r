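Package: mvou
Title: Multivariate Ornstein-Uhlenbeck Models for Phylogenetic Comparative Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multivariate Brownian-motion, Ornstein-Uhlenbeck (OUOU) and
    hierarchical OU/BM (OUBM) models of continuous trait evolution on rooted
    phylogenies. Provides exact trait simulation on trees, a post-order
    pruning likelihood with generalized-least-squares profiling of optima and
    ancestral states, structured drift-matrix constraints (diagonal,
    triangular, custom masks, eigendecomposable classes), small-sample AICc
    model selection with plausibility bands, pooled within-species measurement
    error, parametric bootstrap confidence intervals, and a
    simulation-reestimation pipeline for studying model identifiability and
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
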