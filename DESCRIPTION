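Package: cotscan
Title: Common Off-Target Analysis and dsRNA Design for RNAi Reagents
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Off-target analysis for long-dsRNA RNA interference reagents of
    the kind used in Drosophila and C. elegans screens. Enumerates the ~21-nt
    siRNAs a dsRNA is diced into, maps every gapless alignment with up to
    three mismatches against a transcriptome (unspliced pre-mRNA or spliced
    mature mode) using a word-size-9 seed table, groups siRNAs from one gene
    that share an off-target gene into common-off-target (cot) groups, and
    designs pairs of non-overlapping dsRNA regions predicted to share no
    off-target gene. Includes a deterministic synthetic-genome generator with
    planted off-target structure so the whole pipeline is testable offline,
    and a brute-force search engine used as an independent cross-check.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
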