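Package: ctstrata
Title: Abundance-Stratified Quality Control for High-Throughput qPCR
    MicroRNA Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing and analysing Ct-value data from
    384-well microfluidic qPCR microRNA arrays, with an emphasis on
    formalin-fixed paraffin-embedded (FFPE) versus fresh-frozen tissue
    comparisons. Implements abundance stratification of Ct values into
    high, medium and low strata, duplicate-plate agreement analysis with
    a cubic smoothing spline, well-failure classification and failure-rate
    estimation, abundance-stratified Pearson concordance, chi-square
    tests of stratum-occupancy shifts with cross-stratum migration
    tables, sample-structure analysis (one-minus-Pearson correlation
    distance clustering and principal component analysis), and a
    synthetic-data generator that emulates TaqMan-style array studies
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
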