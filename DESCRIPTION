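Package: divnn
Title: Diversification Parameter Inference from Phylogenies with Ensemble
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based inference of diversification parameters
    (speciation and extinction rates, clade-level carrying capacities, and
    protracted-speciation rates) from reconstructed phylogenetic trees.
    Provides exact Gillespie simulators for constant-rate birth-death,
    diversity-dependent, and protracted birth-death processes conditioned on
    a fixed crown age; encoders that turn trees into graph tensors,
    branching-time sequences, and a 54-element summary-statistic vector;
    three trainable regression networks (a dense network on summary
    statistics, a stacked LSTM on branching times, and a GraphSAGE network
    with differentiable pooling on the tree graph) together with bagging,
    stacking, and sequential residual-boosting ensembles; a crown-age
    conditioned birth-death maximum-likelihood baseline; and evaluation
    protocols covering residual analysis, robustness grids, model
    misspecification, and parametric-bootstrap uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    Matrix,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
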