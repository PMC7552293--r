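Package: sheeppool
Title: Mathematical-Expectation Pooled Genotyping and Population Analysis of a
    Low-Frequency Deletion in Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and simulation of two-stage pooled (group) PCR genotyping
    for low-frequency biallelic indels, with the downstream population-genetic
    workflow used in livestock indel studies: expected-reaction-count design
    curves and optimal pool size, a seeded simulator of the two-stage screen,
    per-breed allele-frequency and diversity statistics (Ho, He, Ne, MAF),
    EM haplotype-frequency estimation with D'/r-squared linkage-disequilibrium
    classification, and nonparametric (Kolmogorov-Smirnov screening,
    Mann-Whitney U) genotype-trait association. Includes a synthetic-data
    module generating Hardy-Weinberg multi-breed populations, non-normal
    growth traits with genotype effects, and two-locus genotypes with
    controllable linkage disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
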