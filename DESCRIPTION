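Package: targetmr
Title: Drug-Target and Genome-Wide Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization with
    cis (drug-target) and genome-wide instrument designs. Reads GWAS
    summary statistics in several column dialects, selects independent
    instruments inside or outside a flanked gene region by p-value
    filtering and greedy LD clumping, harmonizes exposure and outcome
    alleles (including palindromic resolution by allele frequency),
    and estimates causal effects by Wald ratios, fixed- and
    multiplicative-random-effects inverse-variance weighting, and
    MR-Egger regression, with instrument-strength F statistics,
    Cochran's Q heterogeneity, Egger-intercept pleiotropy, and
    simulation-based MR-PRESSO outlier diagnostics. A synthetic
    summary-statistics generator with configurable pleiotropy, LD block
    structure, and implanted outliers makes every stage testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
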