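Package: ncoreg
Title: Windowed Detection of Coordinated Noncoding and Messenger RNA Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A genome-wide screen for gene loci whose mRNA and surrounding
    noncoding RNA are coordinately regulated across a three-condition design
    (baseline, hormone-deprived, drug-treated), as in the adaptation of
    ER-positive breast cancer cells to long-term oestrogen deprivation.
    Implements 100-bp window read counting, median-of-ratios normalization,
    negative-binomial exact testing, merging and classification of
    differential regions into exon/exon-intron/intron/intergene classes,
    a four-way co-regulation screen with chromatin-domain calling and
    gene-length summaries, and FPKM-based k-means expression-pattern
    clustering. Ships a negative-binomial read simulator with planted
    coordinated loci so the whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
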