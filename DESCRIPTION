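Package: eumodel
Title: Embryo-Uterus Models for IVF Cycles with Multiple Embryo Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits two-level Embryo-Uterus (EU) models for in-vitro
    fertilisation (IVF) treatment cycles in which several embryos are
    transferred but only the count of implantations is observed. Success
    requires both a receptive uterus and at least one viable embryo; each
    component is a logistic sub-model and the cycle outcome follows a
    partially observed two-level likelihood. Provides maximum-likelihood
    estimation, likelihood-ratio testing strategies (Found-in-Either,
    Found-in-Both, Bonferroni, Global and pre-specified single tests) for
    patient-level covariates whose sub-model is unknown, AIC/BIC sub-model
    selection with evidence grading of BIC differences, a seeded simulator
    of EU datasets, and a Monte-Carlo study engine for type-I error, power
    and sub-model classification experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    optparse,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
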