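Package: akiflow
Title: Event-Driven AKIN Staging and Renal Dosing Compliance for ICU Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes event-driven acute kidney injury (AKI) stage time series
    for ICU encounters from charted urine output and serum creatinine using the
    AKIN criteria, with MDRD-based back-calculation of baseline creatinine,
    sliding-window weight-normalized urine-output staging, and combination of
    the two stage streams as the maximum of their most recent values. Includes
    an eGFR-based enoxaparin dose-compliance classifier, encounter-level
    outcome metrics (admission/discharge/maximum stage, per-day maxima,
    progression flags, discrete time-to-AKI Kaplan-Meier curves), two-cohort
    comparison statistics (pooled two-proportion z test, summary-statistic t
    test, Fisher-exact power simulation), and a synthetic ICU cohort generator
    with known latent AKI trajectories for end-to-end testing without access
    to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
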