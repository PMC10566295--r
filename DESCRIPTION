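Package: huskGS
Title: Genomic Selection Evaluation for Maize Husk Tightness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate genomic-selection strategies for husk
    tightness (HTI) and kernel dry-down (AUDDC) in structured maize panels.
    Provides trait statistics (HTI, trapezoidal AUDDC), multi-environment
    BLUP and broad-sense heritability via REML, marker quality control and
    linkage-disequilibrium density pruning, six whole-genome regression
    models (ridge-regression BLUP solved by spectral REML, and BayesA,
    BayesB, BayesC, Bayesian LASSO and Bayesian ridge regression fitted by
    single-site Gibbs sampling), Monte-Carlo cross-validation schemes that
    sweep training proportion, marker density and population subgroup
    structure, Duncan multiple-range grouping letters, and a synthetic
    generator of Fst-structured inbred panels with block linkage
    disequilibrium and genotype-by-environment variance for testing the
    whole pipeline without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
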