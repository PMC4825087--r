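Package: termcross
Title: Single-Step Terminal-Cross Genetic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint genetic evaluation of purebred and crossbred performance
    in terminal crossbreeding schemes. Implements a bivariate terminal-cross
    animal model in which the crossbred additive effect is decomposed into
    sire and dam gametic contributions, with pedigree-based (PED) and
    single-step genomic (GEN) variants as well as univariate single-step
    models. Provides pedigree algebra (inbreeding, numerator relationship
    matrices and their sparse inverses), genomic relationship matrices
    (VanRaden, tuning and blending against the pedigree submatrix, H-inverse
    assembly), Bayesian variance-component estimation by Gibbs sampling with
    flat priors, theoretical accuracies of estimated breeding values from
    prediction error variances, sire-blocked cross-validation of predictive
    ability, and a synthetic terminal-cross data generator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
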