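Package: crossres
Title: Predicting Stress Cross-Resistance of Evolved Bacterial Strains
    from Transcriptome Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cross-resistance and collateral
    sensitivity in laboratory-evolved bacterial strains from gene
    expression data.  Implements the expression preprocessing chain
    (quantile normalization, low-expression and variance filters,
    operon-representative selection, per-gene standardization of log10
    expression changes), a per-stress linear model that predicts
    growth-rate changes from a shared gene set, gene-set selection by a
    crossover-free genetic algorithm under repeated 5-fold
    cross-validation, selection-frequency aggregation, and downstream
    summaries (cross-resistance matrices, correlation-based hierarchical
    clustering of expression changes, mutant-versus-resistant growth
    correlations with permutation tests).  A synthetic-data generator
    with planted linear structure supports end-to-end validation against
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    limma,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    withr
Config/testthat/edition: 3
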