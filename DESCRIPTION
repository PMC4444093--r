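Package: carnburden
Title: Rare-Variant Burden, F-Statistics and Haplotype Analysis of
    Carnitine Acyltransferase Gene Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for analysing coding variation in the
    six carnitine acyltransferase genes (CPT1A, CPT1B, CPT1C, CPT2, CRAT,
    CROT) in small founder cohorts such as the Nunavik Inuit. Provides
    genotype-level quality control, Hardy-Weinberg exact testing,
    identity-by-state multidimensional scaling with ancestry-outlier
    flagging, reference-panel based rare-variant classification, per-gene
    mutation-burden statistics with exact binomial and permutation nulls,
    Wright/Nei/Weir-Cockerham/Hudson F-statistics with randomization
    significance, EM haplotype-frequency estimation with D-prime
    confidence-interval LD blocks, and nonparametric comparison of
    deleteriousness scores. A synthetic-cohort simulator generates diploid
    cohorts with exact allele counts or Hardy-Weinberg sampling so that
    every stage is testable without access to individual-level data.
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
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
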