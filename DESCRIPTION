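Package: woundRegulome
Title: Pole-Specific Chromatin Accessibility and Cis-Regulatory Element
    Analysis for Regenerating Wounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for regulatory genomics of wound
    polarity in regenerating planarians. From per-sample ATAC-seq fragment
    intervals it calls nucleosome-free-region peaks, detects anterior- and
    posterior-specific accessible chromatin regions (ACRs) with a
    negative-binomial Wald test, splits ACRs into putative enhancers and
    promoter-like elements using H3K27ac evidence, and classifies the
    accessibility state of each enhancer after notum or wnt1 RNAi
    (accessible, more/less accessible, non-accessible). Merged multi-sample
    peaks are annotated into five cis-regulatory-element classes (core
    promoter, proximal promoter, first intron, proximal and distal enhancer)
    by signed distance to the closest transcription start site. Annotated
    elements are scanned for transcription-factor motifs with an exact
    position-weight-matrix score null, tested for motif over-representation
    against sampled background regions, and summarised into per-gene FoxG
    ratio categories. A moderated-t differential-expression stage integrates
    wnt1 RNAi RNA-seq with TCF/FoxG motif annotations. A seeded synthetic
    wound-regulome generator with a machine-readable truth ledger provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils
Suggests:
    DESeq2,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
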