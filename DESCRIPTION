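Package: npcmf
Title: Nearest-Profile Collaborative Matrix Factorization for
    miRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a binary
    bipartite association matrix by collaborative matrix factorization
    regularized towards nearest-neighbour similarity profiles. Includes
    Gaussian interaction profile (GIP) kernels, MeSH-style directed-acyclic-graph
    disease semantic similarity, kernel fusion, weighted K-nearest-known-neighbour
    (WKNKN) pre-imputation, SVD-initialized alternating least squares,
    pair-masking cross-validation with ROC/AUC scoring, hyperparameter grid
    search, sensitivity sweeps, per-disease candidate ranking, and a synthetic
    data generator with planted low-rank cluster structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
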