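Package: httbind
Title: Latent-Variable Association and Genotype Prediction of Brain
    Serotonin Transporter Binding
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying genetic contributions to regional brain
    serotonin transporter (5-HTT) availability measured by PET binding
    potential (BP_ND). Implements carrier-model recoding of serotonin-related
    variants (including the triallelic 5-HTTLPR system), Hardy-Weinberg and
    X-linked allele-frequency checks, a Gaussian latent-variable model
    relating genotypes and covariates to seven intercorrelated regional
    binding values with FDR-controlled path search and a genotype-block
    likelihood-ratio test, per-region regressions with covariate-adjusted
    percent differences, and a permutation-calibrated cross-validated
    random-forest harness testing whether genotype predicts
    covariate-adjusted binding. A seeded synthetic-cohort generator with the
    same generative structure supports simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest
biocViews: StatisticalMethod, Genetics, Regression, DimensionReduction
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
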