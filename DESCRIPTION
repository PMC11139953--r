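Package: hkgini
Title: Housekeeping Gene Selection from Multi-Tissue Expression Cohorts with Gini Indices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies stably expressed (housekeeping) protein-coding genes
    from multi-tissue, multi-donor bulk RNA-seq cohorts such as GTEx. Gene
    expression inequality is scored with the Gini index along two
    complementary axes: across all pooled donor samples (Gini-subject) and
    across donors within each tissue (Gini-tissue), together with the
    classical tissue-level Gini over per-tissue mean TPMs, the tissue
    specificity index Tau, and the coefficient of variation. The package
    reads GCT v1.2 expression matrices and GFF3 gene annotation (including
    pseudoautosomal PAR-Y deduplication), applies expression filtering,
    threshold-based housekeeping calling on both Gini axes, tissue-pass
    counting, gene-list intersection and sex stratification, and ships a
    seeded synthetic cohort generator with planted gene classes so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
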