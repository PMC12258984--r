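Package: propnet
Title: Network Propagation Proximity Testing, Subnetwork Enrichment, and
    Regulon Activity for Omics Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether a gene or protein list is functionally
    close to a set of disease-associated genes on a molecular interaction
    network. Implements random-walk-with-restart heat diffusion with a
    size-matched permutation null and empirical p-values, extraction and
    hierarchical clustering of induced subnetworks, per-cluster
    hypergeometric overrepresentation with Benjamini-Hochberg FDR,
    differential-expression threshold filters and gene-list set algebra,
    and a transparent weighted-mean permutation z-score for regulon
    (transcription factor or kinase) activity. A synthetic-data layer
    generates stochastic-block-model networks with planted modules, seeded
    gene sets at tunable proximity, differential-statistics tables, gene-set
    collections, and regulons, so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
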