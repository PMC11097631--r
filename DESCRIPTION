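Package: tonotopr
Title: Tonotopy, Tuning, and Sound-Ensemble Analysis for Auditory Cortex Calcium Imaging
Version: 0.1.0
Authors@R:
    person("HirtzLab", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon and widefield calcium imaging of
    the auditory cortex. Filters neurons by peak signal-to-noise ratio,
    classifies frequency tuning by unimodal/bimodal Gaussian fits of
    frequency response areas, quantifies local tonotopic heterogeneity
    (100 micrometre interquartile-range statistic), maps widefield
    best-frequency responses and parcellates subfields via radial
    reversal-point detection, and clusters sound-evoked population vectors
    with UPGMA and a hybrid dynamic tree cut, including cross-session
    stability metrics. Ships a synthetic-data generator with planted ground
    truth (tonotopic gradients, tuning classes, ensemble structure,
    representational drift) so that every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
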