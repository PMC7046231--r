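Package: voa
Title: Explainable Skill Assessment and Formative Feedback for
    Simulation-Based Surgical Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An explainable pipeline for automated assessment of technical
    skill in simulation-based surgical training. Generates synthetic bimanual
    simulator recordings (tool-tip kinematics, applied forces, cumulative
    bleeding), extracts unit-bearing performance metrics, normalizes them to
    z-scores against a training cohort, trains a linear support-vector
    classifier by monotone iterative cost reduction, evaluates it with
    leave-one-out cross-validation, selects metrics by a combined
    forward/backward wrapper search, and decomposes the classifier margin into
    per-metric competency verdicts feeding a two-step, mastery-gated formative
    feedback report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
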