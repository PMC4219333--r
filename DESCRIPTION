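Package: dimerNB
Title: Naive Bayes Prediction of Heterodimeric Protein Complexes from
    Weighted Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Supervised prediction of heterodimeric protein complexes
    (complexes of exactly two distinct proteins) from a reliability-weighted
    protein-protein interaction network.  Protein pairs are described by
    hand-designed features built from three templates (Score, DiffToMax,
    Rank) applied to four pairwise score functions (interaction weight,
    random-walk-with-restarts proximity, and precomputed Gene Ontology
    semantic similarities for the biological-process and molecular-function
    aspects), plus localization agreement and two neighborhood counts.  A
    naive Bayes classifier over equal-width-discretized features with
    Dirichlet pseudocounts scores each pair by a normalized log-likelihood
    ratio.  The package includes symmetric Kullback-Leibler feature
    screening, exhaustive feature-set search by stratified cross-validation,
    overlap-ratio cluster matching metrics, ROC/AUC protocols, and a seeded
    generator of synthetic benchmark bundles with planted heterodimers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
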