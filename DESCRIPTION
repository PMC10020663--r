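Package: crypticall
Title: Detection of Cryptic Intragenic Transcription from Exon-Level RNA-seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting cryptic (intragenic) transcription from
    exon-level RNA-seq count data, a transcriptional signature of H3K36me3
    loss. Provides readers for flattened exon-bin annotation and count
    matrices, a self-contained negative-binomial two-group exon and gene
    test with median-of-ratios normalization, a reason-coded rule cascade
    that locates candidate cryptic transcription start sites from per-exon
    statistics, exact hypergeometric gene-list overlap statistics with
    universe-size calibration, a ground-truth synthetic count simulator for
    end-to-end validation, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
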