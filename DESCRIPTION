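Package: tsnegrad
Title: Gradient-Based Feature Attributions for t-SNE Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes per-sample, per-feature attributions for t-SNE
    embeddings by propagating the partial derivative of each embedded
    point with respect to its own input features through every step of
    the optimizer (a dynamic-programming recursion over iterations).
    Includes exact and Barnes-Hut gradient modes, a corruption-based
    validation framework with neighbourhood-preservation, distance-rank
    and cluster-agreement metrics plus unsupervised and supervised
    feature-importance baselines, a synthetic generator with known
    ground-truth feature dependencies, and utilities to encode a
    multiple sequence alignment into a binary mutation presence/absence
    matrix with quality-control filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    mclust,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
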