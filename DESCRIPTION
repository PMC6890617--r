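Package: drumgs
Title: Genomic Selection and Low-Density SNP Panel Evaluation for Aquaculture Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate genomic selection in aquaculture breeding
    populations such as yellow drum. Simulates SNP genotype and quantitative
    phenotype data with additive polygenic architecture, applies marker
    quality control (minor allele frequency, call rate, Hardy-Weinberg exact
    test), builds the VanRaden genomic relationship matrix, estimates
    variance components and heritability by average-information REML,
    predicts genomic breeding values with GBLUP, ridge-regression BLUP and
    Bayesian-alphabet Gibbs samplers (BayesA, BayesB, BayesCpi and a
    two-component normal mixture), ranks markers with a mixed-model
    association scan to construct informative low-density SNP panels, and
    quantifies predictive ability by repeated random-split cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
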