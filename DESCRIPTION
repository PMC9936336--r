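Package: catrisk
Title: Competing-Risks Validation of Cancer-Associated Thrombosis Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the Khorana and ONKOTEV venous thromboembolism (VTE)
    risk scores from tabular oncology cohorts and validates their prognostic
    performance under competing risks. Provides cohort ingestion with an
    explicit, logged exclusion flow; cumulative incidence of VTE with death
    as a competing event (Kalbfleisch-Prentice product-limit estimator with
    pointwise confidence intervals); Gray's K-sample test; Fine-Gray
    subdistribution-hazard regression with inverse-probability-of-censoring
    weighted risk sets and robust variance; time-dependent ROC/AUC at
    landmark horizons; incidence-rate and events-per-variable planning
    arithmetic; and a calibrated synthetic cohort generator so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    cmprsk,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
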