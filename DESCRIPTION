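Package: spermP2
Title: Sterile-Male-Technique Paternity Analysis for Double-Mating
    Sperm-Competition Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates second-male paternity (P2) from sterile-male-technique
    double-mating experiments in insects. Provides estimation of fertility
    correction factors (normal-male fertility p, residual sterile-male
    fertility z, and the brown-egg misclassification proportion) from mating
    assays stratified by sterilization order and inter-mating interval;
    Boorman-Parker mixture inversion of per-female hatch proportions with
    brown-egg reallocation and exclusion filtering; pooled P2 tables; a
    binomial logit mixed model with an observation-level random effect fitted
    by adaptive Gauss-Hermite quadrature, with marginal means and
    Tukey-adjusted pairwise contrasts; Yates-corrected chi-squared,
    paired t and (mixed) linear-model helpers for mating-behavior
    covariates; and a synthetic-experiment generator with known truth so the
    whole pipeline can be validated by parameter recovery without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
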