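Package: mtgp
Title: Multi-Trait Genomic Prediction and Phenotyping Resource Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying phenotyping resource allocation in plant
    breeding with multi-trait genomic prediction. Provides a synthetic-data
    generator for multi-environment trial phenotypes and SNP genotypes,
    adjustment of raw trial data to per-line best linear unbiased estimates
    (BLUEs) with Piepho-Moehring heritability, SNP quality control and
    expectation-maximisation imputation, the VanRaden realized additive
    relationship matrix, Gibbs samplers for single-trait Bayesian ridge
    regression / G-BLUP and for the multi-trait Gaussian model with an
    unstructured genetic covariance and diagonal residual covariance, and
    the CV1/CV2 cross-validation masking designs (including 50% balanced
    and unbalanced phenotyping of correlated traits and training-size
    sweeps) used to compare phenotyping budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
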