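Package: pgtmosaic
Title: Dual-Platform Detection and Concordance Analysis of Embryo Mosaicism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for preimplantation genetic
    testing for aneuploidy (PGT-A) of mosaic embryos assayed on two platforms
    from one multiple-displacement-amplified (MDA) trophectoderm biopsy.
    Simulates mixed-cell biopsies with a shared whole-genome-amplification
    bias layer and renders SNP-array (LogR/BAF) and low-pass NGS (binned
    read-count) signals from the same amplified product; calls per-arm ploidy
    under SNP-array criteria (BAF scatter plus |LogR| > 0.2) and NGS criteria
    (GC-normalized CNV values classified on the 1.20/1.80/2.20/2.80
    intervals with mosaic level |CNV - 2| x 100); classifies arm-level
    between-platform concordance into five categories; and aggregates cohort
    concordance rates with Pearson chi-square / Fisher exact stratified
    comparisons.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
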