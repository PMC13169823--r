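Package: ocmbtriage
Title: Triage Rules for Oligoclonal IgM Band Testing from CSF/Serum Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate laboratory triage rules that predict
    oligoclonal IgM band (OCMB) positivity in people with multiple sclerosis
    from two surrogate cerebrospinal-fluid/serum indices: the IgM index (IgMi)
    and the free kappa light chain index (FKLCi). Provides albumin-normalized
    index computation, empirical ROC analysis with DeLong confidence intervals
    and paired AUC comparison, specificity-constrained cutoff selection with
    grid snapping, two-marker OR decision rules with exact Clopper-Pearson
    confidence intervals for the diagnostic metrics, the test-sparing PROM
    statistic (percentage reduction of OCMB measurements), and a calibrated
    log-normal synthetic-cohort generator for validating every stage without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
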