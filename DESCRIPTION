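Package: mendelseek
Title: Rare-Disease Gene Discovery by Exome Variant Filtering and
    Cross-Case Intersection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of the exome-intersection strategy
    for dominant/de novo Mendelian gene discovery, as used to identify
    EZH2 mutations in Weaver syndrome. Provides a depth/class/dbSNP/
    pseudogene/panel-of-normals variant filter cascade with per-filter
    attrition reporting, cross-case gene intersection with trio de novo
    confirmation and family segregation checks, an HGVS c.-notation
    parser and consequence classifier with protein-domain, CpG-context,
    conservation, recurrence and last-exon NMD-escape annotation, a
    two-tier splice-disruption consensus built on pluggable
    position-weight-matrix scorers, cohort overgrowth phenotype
    statistics on standard-deviation scores, and a deterministic
    synthetic exome cohort simulator with a planted causal gene so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
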