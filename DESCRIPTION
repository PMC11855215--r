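Package: leanmr
Title: Two-Sample and Multivariable Mendelian Randomization for Lean Mass
    and Height
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) analyses of
    anthropometric exposures, built around the question of whether height
    confounds the genetically proxied association of lean mass with
    Alzheimer's disease and cognitive performance. Implements summary
    statistic input/output, LD-based instrument clumping, allele
    harmonization with frequency-based resolution of palindromic variants,
    the random-effects inverse-variance weighted estimator, MR-Egger
    regression, the weighted median estimator, regression-based
    multivariable MR with conditional F-statistics, and an end-to-end
    pipeline comparing covariate-adjusted, residualized, and multivariable
    adjustment strategies. A synthetic GWAS generator simulates
    individual-level genotypes and phenotypes under the implied causal
    structure so the full pipeline, including the collider bias induced by
    heritable-covariate adjustment, is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
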