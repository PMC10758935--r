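Package: rccsurv
Title: Reliable Change and Session-to-Event Analysis for Youth Behavioral
    Health Coaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how many behavioral health coaching
    sessions precede clinically reliable improvement in youth anxiety and
    depressive symptoms. Implements instrument scoring with screener
    gating (GAD-7, 8-item PHQ-9A with proration, PROMIS pediatric
    T-scores), cohort inclusion filtering with an exclusion ledger,
    Jacobson-Truax reliable-change criteria, construction of first and
    stable reliable-change event times in session units, a from-scratch
    discrete-time Kaplan-Meier estimator with Greenwood variance,
    log-log confidence bands and median confidence intervals, and a
    seeded synthetic-cohort generator so the whole pipeline is testable
    without member-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
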