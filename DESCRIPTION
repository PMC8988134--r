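Package: lpsclass
Title: Classification of LPS Transcriptional Responses Under BET Inhibition
    with Chromatin Accessibility Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis toolkit for RNA-seq and ATAC-seq studies of
    macrophage responses to lipopolysaccharide (LPS) under BET bromodomain
    inhibition. Provides a minimal negative-binomial differential engine
    (median-of-ratios normalization, method-of-moments dispersion, Wald
    contrasts and likelihood-ratio tests), a configurable ten-class
    transcriptional response classification over three pairwise contrasts,
    peak annotation and peak-to-gene linkage within transcription start site
    windows, differential-accessibility enrichment statistics, position weight
    matrix motif scanning, enrichment and similarity clustering, and a seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
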