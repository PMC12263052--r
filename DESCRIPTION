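Package: mrchain
Title: Two-Sample Mendelian Randomization for Causal Chains and Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization along a causal
    chain: reading and harmonizing GWAS summary statistics, selecting and
    quality-filtering genetic instruments (p-value threshold, LD clumping,
    F-statistic filter, confounder exclusion lists), inverse-variance
    weighted, MR-Egger, weighted-median and weighted-mode estimators with
    Cochran Q and Egger-intercept sensitivity statistics, bidirectional
    screening of exposure panels with direction classification, and
    two-step mediation analysis by the product-of-coefficients and
    multivariable-MR difference methods with delta-method standard errors
    and proportions mediated. Includes a seeded generator of GWAS
    summary-statistics triplets with a known structural model for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'conditions.R'
    'estimators.R'
    'gwas-io.R'
    'instruments.R'
    'screening.R'
    'mediation.R'
    'mrchain-package.R'
    'pipeline.R'
    'show-methods.R'
    'simulate.R'
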