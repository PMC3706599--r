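Package: crossgsea
Title: Cross-Platform Gene Set Integration of Transcriptomics and Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates paired-phenotype transcriptomics and proteomics
    experiments through reciprocal gene-set evaluation: entities are ranked by
    the Rank Product statistic within each omics layer, the top differentially
    expressed entities are mapped across platforms via offline identifier
    tables, and the mapped set is screened by gene set enrichment analysis
    (log-fold metric, gene-permutation null) in the complementary layer, with
    leading-edge extraction. Companion analyses include Gene Ontology
    over-representation (Fisher's exact test) and a two-step Rank Product
    meta-analysis, plus a seeded synthetic dual-omics generator with planted
    concordant differential expression for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
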