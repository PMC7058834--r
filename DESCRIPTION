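Package: methylmr
Title: Two-Sample Mendelian Randomization and Multi-Trait Colocalization
    for DNA Methylation and Lung Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Causal-inference toolkit linking smoking, DNA methylation at
    CpG sites, and lung function (FEV1) from GWAS/mQTL summary statistics.
    Implements two-sample Mendelian randomization (Wald ratio, fixed-effects
    inverse-variance weighting, MR-Egger, weighted median, and
    correlated-instrument generalized weighted regression), heterogeneity and
    pleiotropy diagnostics (Cochran's Q with modified weights, the MR-PRESSO
    global test, the Egger intercept), the MR Steiger directionality test,
    two-step and multivariable MR mediation with delta-method standard errors
    and proportion mediated, and three-trait Bayesian colocalization via
    approximate Bayes factors over all fifteen sharing configurations.
    Includes a synthetic-data generator producing two-sample summary
    statistics under configurable causal diagrams with recorded ground truth,
    and a pipeline (discovery, replication, bidirectional, reporting) with
    Bonferroni multiple-testing control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
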