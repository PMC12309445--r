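Package: cuephys
Title: Cue-Evoked Single-Unit and Population Analysis for Discriminative-Stimulus Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings collected during
    discriminative-stimulus (DS) reward tasks: event-locked binning and
    peri-stimulus z-scoring, sliding-window classification of responsive units,
    putative dopamine cell typing, binwise DS+/DS- auROC selectivity with
    trial-shuffle nulls, L1-penalized logistic population decoding with
    repeated train/test splits and feature-frequency selection, and the
    contingency and mean-comparison statistics used to compare groups.
    Includes an inhomogeneous-Poisson session simulator with planted ground
    truth for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
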