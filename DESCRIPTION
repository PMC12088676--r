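Package: ibsdt
Title: Super-Subject Signal Detection Analysis for Inattentional Blindness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Group-level ("super subject") signal detection analysis for
    single-critical-trial inattentional blindness experiments. Provides the
    standard equal-variance sensitivity and bias estimators (d', criterion c),
    the two-alternative forced-choice variant with the 1/sqrt(2) adjustment,
    unequal-variance indices (d_a, c_a), analytic variances and Wald confidence
    intervals for pooled decision matrices, the log-linear (add 0.5) correction,
    exact binomial and Bayesian proportion tests against chance, Holm-Bonferroni
    adjustment, a per-subject critical-trial record pipeline with CSV input and
    output, and a Gaussian-evidence observer simulator for parameter-recovery
    and criterion-variability studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
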