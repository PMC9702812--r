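Package: wearfatigue
Title: Fatigue and Sleep Digital Measures from Continuous Wearable Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for continuous physiological
    signals from chest-worn biosensors (heart rate, R-to-R intervals,
    respiratory rate, skin temperature, steps and posture) linked to
    ecological momentary assessments of fatigue and sleep. Provides
    contextual outlier cleaning of physiological time series, data-coverage
    assessment, windowed statistical aggregation with a full time-domain,
    frequency-domain, geometric and non-linear heart-rate-variability
    feature battery (including Malik normal-to-normal correction),
    least-active 5-hour (L5) rest detection from actigraphy with
    rest-referenced feature normalization, repeated-measures correlation
    against patient-reported outcomes, free-living heart-rate-recovery
    extraction after sustained walking, and group-level ANCOVA with Tukey
    post hoc tests. A synthetic multi-day cohort generator with known
    ground truth makes every stage testable without access to sensitive
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
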