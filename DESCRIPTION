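Package: trialconcord
Title: Concordance Between Randomized Trial and Real-World Cohort Baseline
    Characteristics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether the eligibility criteria of a
    randomized controlled trial (RCT) identify a real-world population that
    resembles the trial population. The package builds eligibility-defined
    cohorts from longitudinal patient records held in a minimal OMOP-like
    data model, pools per-arm RCT baseline characteristics into trial-level
    summaries, and quantifies cohort-trial discrepancy per characteristic
    with a standardized difference for continuous variables and a
    percentage-point difference for discrete variables. A configurable
    synthetic electronic-health-record generator supplies patient-level
    data emulating the marginal structure of four published cardiometabolic
    trials, so the full pipeline runs end to end without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
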