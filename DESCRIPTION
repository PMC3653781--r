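Package: cfsmedip
Title: Testis and Epididymis Promoter Methylation from Cell-Free Seminal DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers testis- and epididymis-specific promoter methylation from
    MeDIP promoter tiling arrays of cell-free seminal DNA by contrasting
    normozoospermic and post-vasectomy profiles. Implements probe-level
    log-ratio normalization, sliding-window one-sided Kolmogorov-Smirnov peak
    calling with peakscores, two-condition peakscore classification of
    promoters, gene-level summarization, MeDIP-qPCR and MethyLight
    quantification with assay controls, Fisher-exact category enrichment with
    Benjamini-Hochberg correction, and a seeded synthetic-data generator with
    planted truth for end-to-end validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
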