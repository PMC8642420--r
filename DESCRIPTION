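Package: targetmr
Title: Drug-Target Mendelian Randomization for Binary Outcomes from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("targetmr", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization toolkit for drug-target
    analyses instrumented on a biomarker, built around cis-acting variants
    in a single gene region. Reads and harmonizes GWAS summary statistics
    and signed LD correlation matrices, LD-prunes instruments and computes
    instrument-strength F-statistics, converts linear-model coefficients on
    binary traits to log odds ratios, estimates causal effects by Wald
    ratio and fixed/random-effects inverse-variance weighting (including a
    generalized-least-squares variant for correlated instruments), pools
    strata by fixed or DerSimonian-Laird random-effects meta-analysis with
    Cochran-Q heterogeneity and between-stratum difference tests, and
    approximates statistical power for binary outcomes. A summary-level
    simulator with known causal effect makes every stage testable without
    access to biobank data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
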