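Package: introgressr
Title: Individual-Based ABBA/BABA Tests, Admixture Proportions and
    Hybrid-Index Analysis for RADseq SNP Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and quantifying historical introgression
    between closely related taxa from reduced-representation (RADseq) SNP
    genotype matrices. Implements exhaustive individual-based ABBA/BABA
    (Patterson's D) tests over all reference-sample combinations with
    both alleles of each diploid sample, admixture proportion f scaled by
    maximal-gene-flow control tests, population-allele-frequency D with a
    binomial bootstrap, reference-sample bias diagnostics, diagnostic-locus
    hybrid index q and inter-source heterozygosity Q12 with
    hybrid-triangle bounds, per-group diversity statistics (allelic
    richness, private alleles, heterozygosity) and pairwise
    Weir-Cockerham Fst with permutation tests, plus a drift-based
    synthetic-data generator with controllable incomplete lineage sorting
    and admixture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
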