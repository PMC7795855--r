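Package: plantcerna
Title: Plant ceRNA Network Inference from Whole-Transcriptome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers miRNA-centric competing endogenous RNA (ceRNA) networks
    from plant whole-transcriptome data under a two-tissue, two-condition
    replicated design. Provides class-specific differential-expression
    filters at fixed fold-change and p-value cutoffs using a
    negative-binomial exact test, lncRNA identification and circRNA locus
    classification, plant miRNA target prediction in cleavage and
    target-mimicry modes, degradome (PARE) cleavage-site validation with
    category 0-4 classification and T-plot tables, and correlation-filtered
    bipartite network assembly with GraphML export. Ships a deterministic
    synthetic whole-transcriptome generator with a machine-readable truth
    table so every stage has a planted-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
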