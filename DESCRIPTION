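Package: gxescan
Title: Genotype-by-Environment Decomposition and Introgression-Block
    Association Scanning for Multi-Environment Drought Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for multi-environment drought phenotype
    analysis in diversity panels: least-squares genotype means and
    drought stress-response indices, AMMI and environment-standardized
    (GGE) decompositions of genotype-by-environment tables with
    sum-of-squares partitioning and biplot coordinates, pairwise-complete
    Pearson correlation structure across experiments, association scans
    of binary 100 kb introgression-block indicators against phenotypes
    with region merging and trait co-location hot-spot detection, and
    one-tailed Fisher's exact (hypergeometric upper-tail) enrichment of
    QTL annotation sets.  Includes a synthetic-data generator that
    emulates a ~20-genotype multi-environment study design with
    controlled variance fractions, missingness, and embedded causal
    introgression windows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    ape,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
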