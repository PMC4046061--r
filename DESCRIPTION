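Package: akiaudit
Title: Acute Kidney Injury Staging and Hospital Cohort Audit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing acute kidney injury (AKI) in hospital
    admission cohorts from longitudinal serum-creatinine data.  Implements
    the RIFLE, AKIN and AKIB creatinine-based staging criteria on
    irregularly sampled laboratory series, four-variable MDRD eGFR
    estimation, baseline renal-function determination with assumed-normal
    imputation, and cohort-level incidence, risk-factor and outcome
    analyses (exact binomial confidence intervals, odds ratios with Woolf
    intervals and mid-p exact tests, logistic risk models, length-of-stay
    comparisons).  A seeded synthetic-cohort generator produces admission
    records and creatinine trajectories with a known AKI stage per
    admission so that the whole pipeline can be exercised and validated
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
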