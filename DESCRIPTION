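Package: inflamr
Title: Inflammation and Mental Health: Dose-Response, Specificity and
    Mendelian Randomisation Analyses on Biobank-Style Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether systemic inflammation, indexed by
    C-reactive protein (CRP) concentration and by genetically predicted CRP
    and interleukin-6 (IL-6) activity, is associated with depression and
    anxiety. Implements quantile (quintile/decile) dose-response regression
    with floating absolute risks, linearity and sex-interaction tests,
    inverse-probability-weighted sensitivity analyses for outcome-dependent
    survey participation (collider bias), bivariate probit likelihood-ratio
    tests of disorder specificity, and one- and two-sample inverse-variance
    weighted Mendelian randomisation with Cochran's Q heterogeneity
    diagnostics. Includes a synthetic biobank-style cohort generator with a
    known causal structure (genotypes, IL-6 activity, CRP, PHQ-9/GAD-7
    symptom scores, outcome-dependent selection) for calibration and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
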