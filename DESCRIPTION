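Package: famliab
Title: Familial Co-Aggregation and Liability-Threshold Modelling of Correlated Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the familial co-occurrence of two correlated
    liability traits (the motivating application is asthma and autism spectrum
    disorder in register and twin data). Provides a synthetic family-registry
    generator with a fully known additive/dominant/shared-environment
    architecture, cluster-robust logistic co-aggregation odds ratios across
    relative types, maximum-likelihood tetrachoric and biserial familial
    correlations, univariate and bivariate ACE/ADE/AE liability-threshold model
    fitting for sibling and twin designs with likelihood-ratio and AIC model
    selection, and a compact LD score regression for SNP heritability and
    genetic correlation from simulated GWAS summary statistics, so that every
    estimator can be validated by parameter recovery against known truths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    sandwich,
    numDeriv,
    digest,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
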