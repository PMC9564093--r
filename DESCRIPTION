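Package: hebbgate
Title: Hebbian Gating Networks and Behavioural Analysis for Compositional
    Cue-Location Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for a compositional generalization
    paradigm in which symbolic cues (five colors crossed with five shapes) map
    onto locations in a circular arena under grid or polar rules. Provides the
    task environment (curricula, block schedules, scoring), two learning
    agents (a vanilla linear effector network trained by SGD and a Hebbian
    gating network with preactivated depression), proper response densities
    over the arena disk for random, unilateral and bilateral policies with
    log-likelihood-ratio scoring and generalizer classification, stagewise
    policy-sequence fitting with random-effects Bayesian model selection,
    performance-matched simulated cohorts, cross-validated inflection-point
    analysis, and cohort-level statistics (uncorrected 2x2 chi-square,
    one-sided bootstrap tests, MAD-based outlier exclusion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
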