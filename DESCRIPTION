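Package: circlequest
Title: Simulation and Analysis of Hidden-Circle Information-Sampling Decision Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for simulating and analysing a family of behavioural
    decision-making tasks in which a fixed-radius hidden circle must be
    localized from binary inside/outside point samples. Implements a discrete
    Bayesian ideal observer over candidate circle centres with an
    expected-error (EE) uncertainty measure, the task's credit economy
    (initial reserve, per-sample cost, per-pixel error cost) with
    expected-value dynamics and optimal sample counts, exponential
    information-extraction-rate fitting, factorial trial-schedule and
    stimulus generators, synthetic participant cohorts with configurable
    reward/uncertainty/effort sensitivities and sampling policies, and an
    estimation pipeline (per-subject logistic sensitivities, group
    contrasts, confidence-calibration slopes, oversampling metrics, and
    robust volume-sensitivity regression with intracranial-volume
    adjustment).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
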