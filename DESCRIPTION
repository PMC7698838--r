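Package: sleepfusion
Title: Multi-Channel Sleep Stage Classification with Residual Attention
    Fusion and Embedded Stage Refinement
Version: 0.1.0
Authors@R:
    person("sleepfusion", "developers", email = "sleepfusion@example.org",
           role = c("aut", "cre"))
Description: Automatic sleep stage scoring of multi-channel polysomnography
    (EEG, EOG, EMG) from 30-second epochs. Implements a multi-branch
    one-dimensional convolutional network with per-channel feature
    extraction, residual self-attention channel fusion, and an embedded
    previous-stage refinement head trained by teacher forcing; checkpoint
    ensembling, leave-one-subject-out evaluation, rule-based and hidden
    Markov model hypnogram smoothing baselines, transition/nontransition
    stratified metrics, and a stage-conditioned synthetic signal simulator
    so the whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
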