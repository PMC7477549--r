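Package: cytomap
Title: Tissue-Specific Expression, eQTL Direction and GWAS Integration for Cytokine Gene Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for characterizing a curated catalog of
    cytokine and cytokine-receptor genes: tissue-specificity scoring of median
    expression matrices (Tau and TSI), summarization of significant cis-eQTL
    landscapes per gene and tissue, directional classification of shared eQTL
    effects on physically clustered gene pairs, Jaccard tissue-similarity of
    direction-signed eQTL signatures, and integration of GWAS-catalog
    associations with linkage-disequilibrium proxies, functional scores and
    positive-selection statistics. Includes a synthetic-data generator with
    planted, recoverable structure so every stage is testable without external
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
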