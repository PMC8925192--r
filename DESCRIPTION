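Package: blgscreen
Title: Phenotypic-Outlier Screening for Beta-Lactoglobulin Isoforms in Bovine Milk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterising low-expression alleles of
    bovine beta-lactoglobulin (BLG) from high-throughput milk screens. Quantifies
    the BLG A and B protein isoforms from flow-injection electrospray mass
    spectra via their 10+ to 13+ charge-state envelopes, classifies genotypes
    from the A-vs-B concentration plane, fits a two-component Gaussian mixture
    to B:A ratios in half-sib families to detect segregating expression alleles,
    estimates allele-specific expression from RNA-seq allele counts with
    bootstrap uncertainty, runs a desk-scale single-variant association scan
    with an optional genomic relationship matrix, and summarises milk
    composition by genotype with ANOVA letter displays. Includes a seeded
    synthetic-data generator that emulates pedigreed cow populations, isoform
    concentrations, mass spectra, allele counts and milk-composition records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    multcomp,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
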