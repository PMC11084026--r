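Package: akitraj
Title: Early Creatinine Trajectory Classes in Sepsis-Associated Acute Kidney Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies acute kidney injury (AKI) in critically ill patients with
    sepsis by the shape of the serum-creatinine trajectory over the first 96 hours
    of intensive-care admission. Provides a synthetic ICU cohort generator,
    rule-based Sepsis-3 and KDIGO phenotyping (suspected infection, sepsis onset,
    reference creatinine with MDRD back-calculation, AKI detection and staging,
    cohort selection, acute kidney disease outcomes), a latent class mixed model
    fitted by an expectation-maximisation algorithm with BIC class-number
    selection, posterior class assignment and external-cohort application, and
    class-versus-outcome association analysis (logistic regression for acute
    kidney disease, Cox and Kaplan-Meier models for composite outcomes, with
    predictive-mean-matching multiple imputation and Rubin pooling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
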