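Package: cisnat
Title: Identification and Classification of Cis-Natural Antisense Transcript Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotation-driven identification of sense/antisense gene pairs
    from a gene-level annotation table (GTF or CSV). Classifies pairs into
    eight structural types (four overlapping: head-to-head, embedded, fully
    overlapped, tail-to-tail; four non-overlapping: nearby/faraway
    head-to-head and tail-to-tail), extracts pairs whose antisense TSS or TES
    falls in a signed window relative to the sense anchor, profiles
    divergent/convergent transcription in fixed-width offset bins split by
    RNA biotype, and screens sense/antisense pairs for correlated expression
    over a TPM time course (Spearman rank correlation, count-based offset
    bins, a random same-chromosome null, and the Dwass-Steel-Critchlow-Fligner
    all-pairs rank test). Includes seeded synthetic-fixture generators that
    plant pairs of every structural type and expression matrices with planted
    correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    S4Vectors,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
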