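Package: chbstroke
Title: Two-Sample Mendelian Randomization of Chronic Hepatitis B on Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for two-sample Mendelian randomization of
    chronic hepatitis B (exposure) on stroke and its TOAST subtypes
    (outcomes) in East Asians: GWAS summary-statistic readers, allele
    harmonization with a full audit trail, greedy LD clumping,
    inverse-variance-weighted and MR-Egger estimators in both independent-
    and correlated-instrument forms, the weighted median estimator with
    bootstrap standard errors, Cochran's Q and Egger-intercept sensitivity
    tests, Bonferroni multiple-testing control, and a synthetic
    summary-statistics generator with known causal effect, pleiotropy and
    linkage-disequilibrium structure so every stage is testable at desk
    scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
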