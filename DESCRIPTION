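Package: lipoloci
Title: Shared Genetic Loci for Anthropometric Traits and Adipocyte Lipolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for identifying genetic loci shared
    between anthropometric traits (body mass index, waist-hip ratio
    adjusted for BMI) and adipocyte lipolysis phenotypes from GWAS
    summary statistics. Provides allele harmonization with palindromic
    SNP handling, direction-rule overlap scanning at nominal
    significance, eQTL-based candidate-gene classification with
    expression filtering in adipose-derived stem cells, exact binomial
    tests of directional enrichment, and a two-sample Mendelian
    randomization estimator suite (Wald ratio, inverse-variance
    weighted, MR-Egger with bootstrap, weighted median, weighted mode
    with and without the NOME assumption, and the I2-GX instrument
    strength diagnostic). Includes a summary-statistics simulator with
    known causal architecture for method validation, and packaged
    tables of shared BMI- and WHRadjBMI-lipolysis loci.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
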