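Package: gcplastid
Title: Guard-Cell Chloroplast Morphometry and Pairing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of plastid populations in stomatal guard
    cells of Arabidopsis plastid-division mutants. Classifies chloroplasts
    into size classes (giant, normal, mini), types guard cells by their
    chloroplast content, summarises size-class frequencies, length
    statistics and per-cell chloroplast counts, and tests whether the two
    guard cells of a stoma share their type more often than expected under
    a uniform random perfect matching of cells into pairs (a seeded
    Monte-Carlo null with a closed-form expectation and empirical
    p-values). Includes a calibrated synthetic-data generator that emulates
    the published per-genotype population statistics so the whole pipeline
    is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
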