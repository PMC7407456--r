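Package: gxeblup
Title: Multi-Environment Genomic Prediction with Genotype-by-Environment
    Reaction-Norm GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reaction-norm GBLUP models for multi-environment trials of
    inbred crop lines: a Bayesian mixed model with environment, line,
    genomic and genomic-by-environment random effects whose covariance is
    the Hadamard product of a marker-derived relationship matrix and the
    environment incidence structure. Variance components and genomic
    estimated breeding values are obtained by Gibbs sampling; prediction
    ability is assessed under CV1 (untested lines) and CV2 (sparse
    testing) cross-validation. Includes marker quality control, genomic
    relationship matrices, adjusted line means, heritability and
    selection-response calculations, and a synthetic-data generator for
    structured inbred panels and bi-parental doubled-haploid populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    lme4,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
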