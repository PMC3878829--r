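Package: srnapipe
Title: Small RNA-Seq Read Processing, Annotation and Differential
    Expression
Version: 0.4.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for single-end small RNA sequencing
    data: error-tolerant 3' adapter trimming with quality and length
    filtering, read collapsing, hierarchical annotation of reads against
    ordered small non-coding RNA reference libraries with isomiR
    classification, statistical count filtering, fold-changes damped by an
    additive median correction factor, no-replicate differential
    expression by quantile normalization and Fisher's exact test, sample
    clustering and principal component analysis, seed-based miRNA target
    site prediction (8mer, 7mer-m8, 7mer-A1), and a fully seeded
    synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
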