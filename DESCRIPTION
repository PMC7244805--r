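Package: gradientpanmixia
Title: Population-Genomic Tests of Panmixia and Isolation by Environment
    Across Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether dispersal is reduced across steep
    environmental gradients using reduced-representation SNP data. The
    package implements a reproducible SNP filter cascade for called
    variants, core population-genetic statistics (Weir-Cockerham FST,
    genotype PCA, LD pruning, folded site frequency spectra, per-locus
    theta from homozygosity), a Bayesian model of allele-frequency
    covariance decaying with geographic and environmental distance fitted
    by adaptive Metropolis-Hastings MCMC, coalescent simulation of the
    site frequency spectrum under constant-size and exponential-growth
    demographies with rejection approximate Bayesian computation for
    model choice, and range-limit diagnostics (theta versus range
    position, Rousset regression for Wright's neighborhood size). A
    seeded synthetic-data generator emulates elevational sampling designs
    so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    geosphere,
    lme4,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
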