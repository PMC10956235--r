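Package: npcplan
Title: Automatic IMRT Planning for Nasopharyngeal Carcinoma via Fluence
    Prediction and Plan Fine-Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, end-to-end implementation of automatic nine-beam IMRT
    plan generation for nasopharyngeal carcinoma: a seeded synthetic
    head-and-neck phantom with five nested/lateral planning target volumes and
    seventeen organs at risk, a surrogate fluence predictor, a simplified
    pencil-beam dose-influence engine, automatic derivation of dose-mimicking
    optimization objectives (dose-at-volume and generalized equivalent uniform
    dose) from the predicted-fluence plan, projected-gradient fluence
    fine-tuning with warm or cold start, step-and-shoot multi-leaf collimator
    sweep sequencing, and plan-quality evaluation (DVH, conformity and
    homogeneity indices, paired plan comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
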