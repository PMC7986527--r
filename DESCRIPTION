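Package: rpfeedback
Title: Readiness-Potential Neurofeedback: Simulation, Single-Trial Scoring
    and Group Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for closed-loop neurofeedback studies of the readiness
    potential (Bereitschaftspotential). Provides a synthetic generator for
    multi-channel EEG and 3-axis accelerometry with known per-trial ground
    truth; accelerometer-based movement-onset detection with a linear
    classifier on log-variance features and a backward sliding-window
    search; RP-informative channel selection; single-trial RP scoring with
    a shrinkage-regularized (Ledoit-Wolf) linear discriminant and
    leave-one-out score calibration; a causal replay of the 20-ms feedback
    loop with the trial and participant exclusion rules; and the two-level
    statistical analysis of feedback scores, including directional and
    two-sided JZS Bayes factors for one-sample t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
biocViews: ElectroEncephalography, Classification, TimeCourse, Bayesian
RoxygenNote: 7.3.3
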