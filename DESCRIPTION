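Package: dynAgeNet
Title: Weighted Dynamic PPI Subnetworks for Supervised Prediction of
    Aging-Related Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers aging-specific subnetworks from an entire
    context-unspecific protein-protein interaction network and an
    age-series gene expression table, either as induced subgraphs on
    active genes or by activity-biased network propagation (random walk
    with restart, edge flux). Builds weighted dynamic subnetworks whose
    edge weights are percentage changes of normalized propagated weights
    between consecutive ages, extracts weighted dynamic node features
    over four edge neighborhood types (weight-count, Pearson-correlation
    and Cramer-von Mises encodings, raw or binned), and evaluates a
    supervised model grid (logistic regression, naive Bayes, SVM-rbf,
    with optional PCA) by stratified cross-validation with AUPR-based
    model selection, permutation baselines, prediction-overlap and
    cancer-list validation. Includes a seeded synthetic-data generator
    with a plantable aging signal for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, GeneExpression, Classification,
    NetworkInference
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'dynAgeNet-package.R'
    'utils.R'
    'io.R'
    'netwalk.R'
    'subnetworks.R'
    'features.R'
    'prediction.R'
    'synthetic.R'
    'pipeline.R'
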