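Package: cispair
Title: Screening for Putative Cis-Regulatory lncRNA/Coding Gene Pairs in
    Pan-Cancer Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds proximal coding/lncRNA and coding/coding gene pairs from a
    genome annotation at configurable distance windows, classifies lncRNA
    orientation relative to the coding anchor, filters likely alternative
    polyadenylation artifacts, and screens each pair for monotone expression
    association (Spearman) across tumor samples within each cancer type with
    Benjamini-Hochberg correction. Pairs are aggregated across cancer types
    into negatively and positively correlated sets (LCN/LCP for lncRNA/coding,
    CCN/CCP for coding/coding controls) and characterized by Tau expression
    specificity, exonic sequence conservation with coding-exon masking,
    subcellular localization (RCI), gene-category enrichment, and coupling
    between lncRNA expression and promoter methylation. A synthetic-cohort
    generator with a ground-truth manifest makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
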