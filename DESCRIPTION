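Package: mrkit
Title: Two-Sample Mendelian Randomization with Multivariable and
    Bayesian Model-Averaging Extensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS
    summary statistics: reading and validating summary files and LD
    matrices, allele harmonization with palindromic-variant handling,
    instrument selection by significance screening and greedy LD
    clumping, simulation-based pleiotropic-outlier detection,
    single-variable estimators (Wald ratio, inverse-variance weighted,
    Egger regression, weighted median) with heterogeneity and
    pleiotropy diagnostics, multivariable MR (IVW, Egger, and
    LASSO-based valid-instrument selection), Bayesian model averaging
    over exposure subsets with influence diagnostics, fixed-effect
    meta-analysis, and a summary-statistics simulator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
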