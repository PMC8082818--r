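Package: ptDE
Title: Differential Expression Along Single-Cell Pseudotime with
    Uncertainty Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests for genes whose expression changes along inferred
    single-cell pseudotime while accounting for the uncertainty of the
    pseudotime inference itself. Cells are repeatedly subsampled, the
    user-supplied pseudotime method is re-run on every subsample, and each
    subsample's pseudotime is permuted to build a gene-specific null
    distribution of a spline-based test statistic from negative-binomial
    (optionally zero-inflated) generalized additive models. Null statistics
    are summarized empirically and by a gamma or two-component gamma
    mixture fit, yielding calibrated empirical and parametric p-values.
    Includes a lineage count-data simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
biocViews: SingleCell, GeneExpression, DifferentialExpression,
    Regression, Software
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    mgcv,
    fitdistrplus,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    parallel
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
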