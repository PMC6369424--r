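Package: airplan
Title: Asthma Action-Plan Zone-of-Control Engine and mHealth Utilization
    Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision engine and analytics toolkit for guideline-driven
    asthma collaborative self-management platforms.  Implements the
    traffic-light zone-of-control algorithm (symptom- and peak-flow-based,
    with insufficient-data handling and post-action-plan reset), a
    rule-based email reminder planner with rotating message bodies, Air
    Quality Health Index risk banding, an append-only typed event log with
    CSV/JSON-lines round-trip, cohort utilization analytics (per-patient
    per-week rates, weekly-active attrition curves, time-of-day histograms,
    zone distributions, good-day summaries, System Usability Scale and
    Likert scoring, rank-sum subgroup comparison), and a seeded synthetic
    cohort simulator with engagement decay, reminder response, and
    clinic-visit surveillance effects so the full pipeline can be exercised
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
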