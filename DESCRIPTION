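Package: ocrtime
Title: Integrative Analysis of RNA-Seq and ATAC-Seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the joint analysis of bulk RNA-Seq and ATAC-Seq
    across differentiation time points: median-of-ratios normalization,
    negative-binomial differential expression with a fold-change/FDR/FPKM
    gene-calling rule, temporal hierarchical clustering and hypergeometric
    gene-set enrichment, lncRNA composition and lncRNA-target co-expression
    statistics, consensus open-chromatin-region construction, annotation and
    differential accessibility, accessibility-expression integration, and
    position-weight-matrix motif scanning with exact score p-values.
    Includes a fully deterministic synthetic-data generator that emulates
    the statistical structure of a three-time-point dopaminergic
    differentiation study, so the whole pipeline can be exercised and
    calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
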