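Package: trialcea
Title: Trial-Based Cost-Effectiveness and Cost-Utility Analysis for a
    Two-Arm Insomnia Intervention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Health-economic evaluation pipeline for a two-arm randomized
    trial of guided internet-based cognitive behavioural therapy for
    insomnia against a wait-list control. Converts self-reported resource
    use into per-participant costs under societal and public-health-care
    perspectives (human-capital absenteeism, Osterhaus and HLQ
    presenteeism, opportunity- and replacement-cost valuation, consumer
    price indexation and purchasing-power-parity conversion), computes
    symptom-free status from the Insomnia Severity Index and
    quality-adjusted life years from SF-6D utilities by area under the
    curve, estimates incremental costs and effects with bootstrapped
    seemingly unrelated regressions and bias-corrected and accelerated
    confidence intervals, and derives decision analytics: incremental
    cost-effectiveness ratios with acceptability intervals,
    cost-effectiveness plane quadrant distributions, and acceptability
    curves. Includes a calibrated synthetic cohort generator and a
    sensitivity-scenario runner so the full pipeline is testable without
    access to participant-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
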