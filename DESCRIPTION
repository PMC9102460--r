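Package: thermolnc
Title: Long Non-Coding RNA Discovery and Regulatory Network Analysis for
    Floral Thermogenesis Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for the downstream analysis of strand-specific
    RNA-seq transcript catalogues from thermogenic floral tissue sampled
    across developmental stages. Identifies long non-coding RNAs (lncRNAs)
    by consensus voting over four coding-potential evidence channels,
    profiles stage presence and transcript characteristics, screens
    differentially expressed lncRNAs between stages with a pooled
    two-proportion test and Benjamini-Hochberg correction, assigns cis
    target genes by a strand-aware genomic window with a dual
    correlation gate, detects trait-correlated co-expression modules via
    soft-threshold adjacency, topological overlap and module eigengenes,
    and infers competing endogenous RNA (ceRNA) networks and endogenous
    target mimics (eTMs) by a hypergeometric shared-miRNA test. A seeded
    synthetic-data generator with planted ground truth emulates the
    5-stage x 3-replicate receptacle design so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
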