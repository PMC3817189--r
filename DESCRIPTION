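Package: cgsa
Title: Correlated Gene Set Analysis for Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised extraction of disjoint, positively co-expressed
    gene sets (correlated gene sets, CGSs) from a variance-stabilised
    expression matrix, with the downstream machinery to use them: per-set
    summary scores built from permutation-invariant weights, angular
    ordering of samples on the principal plane, projection of external
    samples, cross-platform mapping of set collections, partitioning around
    medoids with silhouette-based selection of the number of clusters,
    level-controlled association testing of set summaries against
    phenotypes via single-step max-T permutation adjustment, gene-wise
    generalized log-ratio and differential-expression utilities with
    class-partitioned density decompositions, hypergeometric and parametric
    (PAGE) gene set enrichment, and a latent-factor cohort simulator with
    truth-recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
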