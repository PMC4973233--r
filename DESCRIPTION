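Package: mriv
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization analyses of a
    continuous exposure on a binary outcome using GWAS summary statistics.
    Reads and validates summary-statistics tables, harmonizes exposure and
    outcome records to a common effect allele (including palindromic-variant
    resolution by allele frequency), and estimates the causal effect with
    Wald ratios, the inverse-variance weighted estimator, a profile
    likelihood estimator, the weighted median estimator, and MR-Egger
    regression with its directional-pleiotropy intercept test. Includes
    Cochran's Q and I-squared heterogeneity statistics, fixed-effects
    meta-analysis of study-level effects, weighted allele-score validation
    on individual-level data, power and minimum-detectable-odds-ratio
    calculations for binary outcomes, and a synthetic GWAS data generator
    for end-to-end testing of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
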