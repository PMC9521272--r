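Package: cdaNetFuse
Title: Ensemble Network Prediction of circRNA-Disease Associations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores circRNA-disease pairs by an ensemble of random walk with
    restart on a heterogeneous circRNA-disease network and Laplacian
    regularized least squares in circRNA and disease space. Circular RNA
    similarity is built by fusing functional similarity (best-match averaging
    over disease semantic similarity) with Gaussian association-profile
    kernel similarity; disease similarity fuses a precomputed semantic
    similarity matrix with the profile kernel. The package evaluates itself
    by repeated k-fold cross-validation with rank-based AUC over held-out
    association pairs, ranks candidate circRNA biomarkers per disease, and
    ships a planted-cluster synthetic data generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'cdaNetFuse-package.R'
    'crossval.R'
    'ensemble.R'
    'hyperparams.R'
    'io.R'
    'lrls.R'
    'rwr.R'
    'similarity.R'
    'synthetic.R'
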