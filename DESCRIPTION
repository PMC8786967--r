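Package: teregkit
Title: Transposable-Element Regulatory Genomics Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for transposable-element (TE) regulatory
    activity: copy-level TE differential expression with subfamily ranking,
    solo versus proviral LTR classification, TE-subfamily enrichment in open
    chromatin against a genomic-distribution-matched permutation null,
    fixed-bin differential methylation calling and TE methylation
    metaprofiles, mismatch-tolerant CRISPRi guide target scanning with
    priority annotation, and region-associated differential-gene distance
    analysis. Ships a seeded toy-genome simulator with a planted-truth
    manifest so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
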