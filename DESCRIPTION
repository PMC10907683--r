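Package: phenofuse
Title: Multimodal Fusion of Smartphone Keyboard Dynamics, Accelerometry and
    Daily Self-Report via Temporal ICA and Mixed-Effects Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated digital-phenotyping pipeline for dense longitudinal
    smartphone data. Raw keypress event streams are segmented into typing
    sessions and summarised into daily keyboard-dynamics features (inter-key
    delay statistics, autocorrect and backspace rates, typing volume);
    in-session accelerometer traces are low-pass filtered with a zero-phase
    Butterworth filter and classified into daily movement and upright rates;
    high-dimensional daily Likert self-report panels are log-transformed,
    concatenated across participants along the time axis and decomposed with
    temporal independent component analysis (symmetric FastICA, logcosh
    contrast); and the resulting independent components are fused with the
    passive features through linear mixed-effects models with random
    intercepts per participant and per week nested within participant, under
    a family-wise Bonferroni correction. A fully parameterised synthetic-study
    generator with known ground truth (mixing matrix, fixed effects, variance
    components) makes every stage and the end-to-end pipeline testable
    without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    signal,
    lme4,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
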