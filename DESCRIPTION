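Package: ribofam
Title: Vertebrate Ribosomal Protein Families, Sequence Conservation and
    Cross-Species Tissue Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-arm survey of vertebrate ribosomal proteins
    (RPs). The sequence arm masks low-complexity regions, performs exact
    Smith-Waterman all-vs-all comparison with Karlin-Altschul E-values,
    builds percent-identity similarity networks, clusters them with a
    from-scratch Markov clustering (MCL) implementation, and scores
    within-family sequence conservation between reference species. The
    expression arm ingests GTEx-style GCT and cRPKM tables, applies
    per-gene or per-organism Min-Max scaling, summarises expression by
    tissue category, trains nested cross-validated multiclass tissue
    classifiers (logistic regression, linear and RBF SVM, random forest),
    and evaluates cross-species transfer of tissue signal with an exact
    one-tailed binomial test. A synthetic-data module generates protein
    families and expression matrices with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    Rtsne,
    dplyr,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
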