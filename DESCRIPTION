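Package: circout
Title: Circadian Transcriptional Output at Transcription-Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Meta-analysis toolkit for relating clock transcription-factor
    DNA binding to circadian transcriptional output. Derives high-confidence
    co-bound ChIP-Seq peaks, assigns peaks to genes with strand-aware
    promoter/gene-body windows, aggregates read-level signal in peak-centered
    windows normalized per 100 million reads, fits 24-hour rhythms by
    harmonic (Fourier) regression, classifies each target gene's
    transcriptional output (in-phase rhythmic, out-of-phase rhythmic,
    arrhythmic, not expressed, post-transcriptional, low expression, no
    signal), applies reference-set mean and ranking (quantile) normalization
    across time points, and computes a decile-based transcription-factor DNA
    binding variability index with Kruskal-Wallis/Dunn compact-letter group
    comparisons. Includes a seeded synthetic-data generator so every stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    generics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
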