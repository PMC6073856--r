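Package: cernachill
Title: Competing Endogenous RNA Network Inference for Cold-Stress
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for coding and non-coding RNA analysis
    of two-group (control versus chilled) expression experiments.  Provides
    negative-binomial differential-expression calling with
    Benjamini-Hochberg false-discovery-rate control and class-specific
    significance rules for mRNAs, lncRNAs, circRNAs and miRNAs; positional
    classification of novel long non-coding RNAs (lincRNA, antisense,
    sense, intronic) against a reference annotation; hypergeometric testing
    of shared-miRNA (competing endogenous RNA) relationships between
    transcript pairs with filtering and connected-component network
    extraction; central and Wallenius non-central hypergeometric category
    enrichment with isotonic length-bias correction; and a synthetic-data
    generator that produces count matrices, miRNA-target interaction maps
    and toy genome annotations with recorded ground truth, so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
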