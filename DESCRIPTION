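Package: xaiPrognosis
Title: Explainable Deep Learning Prognosis from Frontoparietal fMRI Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts one-year symptomatic improvement in early psychosis from
    protocol-adjusted frontoparietal fMRI activation betas. Implements
    Improver/continuous outcome construction from Brief Psychiatric Rating
    Scale (BPRS) totals, protocol-version adjustment by standardized
    residualization, a repeated 90/10 holdout comparison harness over six
    shallow learners and a multilayer perceptron trained with Adam, paired
    McNemar tests, and an explainable-AI stage that binarizes neuron
    activations, solves a disjoint set-cover integer program over them, and
    emits disjunctive-normal-form threshold rules. Ships a seeded synthetic
    cohort generator with a planted single-feature rule for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    randomForest,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
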