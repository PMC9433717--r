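Package: predbench
Title: Benchmarking of Variant Pathogenicity Prediction Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks computational pathogenicity predictors for missense
    variants from annotated VCF files. Builds labelled benchmark cohorts with
    ClinVar/gnomAD-style filter chains, ranks tools by the coverage-weighted
    normalized Matthews correlation coefficient and by auROC on rank-transformed
    scores, recalibrates disease-specific decision thresholds by F-beta grid
    optimization with stratified bootstrap intervals, controls type-I
    circularity by training-set exclusion, and prioritizes variants of unknown
    significance by top-tool ensemble agreement. Ships a synthetic cohort
    generator with known class-conditional score distributions so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
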