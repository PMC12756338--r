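Package: clustmed
Title: Causal Mediation Analysis with Many Mediators in Family-Clustered Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression-based causal mediation analysis of a binary exposure on
    continuous outcomes through multiple continuous mediators in cluster-correlated
    (family) data. Fits marginal linear mediator and outcome models by generalized
    estimating equations with an exchangeable working correlation and cluster-robust
    (sandwich) standard errors, combines them by the product-of-coefficients method
    into direct, per-mediator indirect, combined indirect and total effects and the
    mediated proportion, and attaches Efron percentile confidence intervals from a
    cluster (family) bootstrap. Includes backward stepwise AIC selection of mediators
    for a secondary analysis, APOE genotype-group derivation from SNPs rs7412 and
    rs429358, mediator preprocessing (log-transform and standardization), and a
    family-structured synthetic cohort generator with known mediation structure for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
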