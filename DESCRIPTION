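Package: patsim
Title: Patient Similarity Clustering and Enrichment Analysis for Variant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds log2-transformed gene-sharing patient similarity matrices
    from literature-derived variant event tables, clusters subjects by
    complete-linkage hierarchical agglomerative clustering, labels clusters by
    their density factor, partitions cluster-shared variants into the seven
    regions of a three-set Venn decomposition, and scores gene-set
    over-representation (Fisher's exact test, fold enrichment,
    Benjamini-Hochberg FDR) together with observed-versus-expected
    interaction-edge counts against a background network. Ships a seeded
    synthetic cohort generator with planted cluster structure and planted
    enriched terms so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    dplyr,
    jsonlite,
    mclust,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
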