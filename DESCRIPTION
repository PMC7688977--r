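Package: fedsurv
Title: Privacy-Preserving Federated Survival Analysis for Multi-Registry
    Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting Cox proportional-hazards models across several
    cancer registries without pooling patient-level data. Each site runs a
    node that answers computation tasks with aggregate statistics only
    (per-event-time risk-set sums); a coordinating server performs
    Newton-Raphson updates of the partial likelihood with Breslow's method
    for tied event times. Includes registry cohort derivation (ICD-O-3
    topography/morphology selection, survival and covariate coding,
    hospital-volume categories), federated descriptive statistics and
    chi-square comparisons, country-by-factor interaction likelihood-ratio
    tests with per-country hazard ratios, a two-registry synthetic data
    generator, and an end-to-end study driver with a payload audit that
    enforces the aggregate-only contract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
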