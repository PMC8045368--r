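Package: wgsbench
Title: Benchmarking Toolkit for Clinical Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates clinical whole-genome sequencing pipelines against
    truth sets. Provides genotype-stratified concordance of small-variant
    calls within high-confidence regions (sensitivity, PPV, specificity,
    accuracy) with genotype-quality and depth gating, copy-number-variant
    benchmarking by reciprocal overlap including a miss-detection-index
    statistic across sequencing depths, breadth-of-coverage analysis over
    disease-gene panels and CNV regions, construction and evaluation of
    Mendelian trio-derived truth sets, a rule-based compiler for
    disease-associated gene lists, and seeded synthetic-data generators with
    known ground truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
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
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
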