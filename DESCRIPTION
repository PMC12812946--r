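Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling for Advanced
    Breast Cancer Regimens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-state (progression-free, progressed, dead)
    partitioned survival cost-utility pipeline for first-line
    PIK3CA-mutated HR+/HER2- advanced breast cancer regimens
    (inavolisib plus palbociclib-fulvestrant versus
    palbociclib-fulvestrant). Provides a calibrated synthetic two-arm
    trial generator, reconstruction of pseudo individual patient data
    from digitized Kaplan-Meier coordinates and numbers at risk
    (the Guyot interval algorithm), Royston-Parmar restricted cubic
    spline survival models on the log cumulative hazard scale with
    AIC/BIC model selection, discounted state-occupancy traces with
    half-cycle correction, cost and QALY accrual with incremental
    cost-effectiveness statistics, one-way deterministic and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and price, time-horizon, utility and
    regional willingness-to-pay scenario analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    flexsurv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
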