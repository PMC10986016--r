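Package: twostepmr
Title: Two-Step Two-Sample Mendelian Randomization Mediation Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two-sample Mendelian randomization (MR) mediation
    studies on GWAS summary statistics: instrument selection by significance
    and LD clumping with R-squared/F instrument-strength metrics, effect-allele
    harmonization across traits, a suite of univariable causal-effect
    estimators (inverse-variance weighted, MR-Egger, weighted median, simple
    and weighted mode, robust adjusted profile score), heterogeneity and
    pleiotropy diagnostics (Cochran's and Rucker's Q, Egger intercept,
    MR-PRESSO outlier detection, leave-one-out), multivariable MR for
    mediator direct effects, and product-of-coefficients mediation
    decomposition with delta-method confidence intervals. Includes a
    generator of synthetic GWAS summary statistics from a known mediation
    causal diagram so every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
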