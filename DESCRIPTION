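Package: tdcsdcm
Title: Dynamic Causal Modelling of tDCS-Modulated Frontal Effective Connectivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Effective-connectivity analysis of concurrent transcranial
    direct current stimulation (tDCS) and fMRI picture naming. Implements a
    two-region bilinear dynamic causal model with a balloon-Windkessel
    haemodynamic forward model, variational-Laplace model inversion, fixed
    effects Bayesian model selection over a crossed six-model space,
    sampling-based Bayesian model averaging, a two-distribution test for
    condition differences in connection strength, self-connection half-life,
    reaction-time cleaning and condition tests, and the brain-behaviour
    correlation between connectivity change and naming facilitation. A
    synthetic cohort generator reproduces the study design (event timing,
    session structure, planted condition effects and a plantable
    connectivity-behaviour correlation) so the whole pipeline is testable
    without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
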