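Package: glioscope
Title: Glioma MRI Classification with Single-Candidate Hyperparameter
    Optimization
Version: 0.1.0
Authors@R:
    person("Glioscope", "Maintainers", email = "maintainers@glioscope.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a
    resource-aware MRI classification pipeline for adult-type diffuse
    glioma subtyping from single axial T2-weighted slices. Provides the
    Single Candidate Optimizer (SCO) and its advanced variant (ASCO, with
    opposition-based initialization and a Chebyshev chaotic stream), a
    small MnasNet-style convolutional network built from mobile inverted
    bottleneck (MBConv) blocks with squeeze-and-excitation gating, an
    SGD-with-momentum trainer, CLAHE contrast enhancement and an
    augmentation catalogue, a seeded synthetic T2-like phantom generator,
    patient-level stratified splitting with leakage guards, the full
    confusion-matrix metric suite including the Matthews correlation
    coefficient, and an end-to-end hyperparameter-search pipeline scored
    by a composite accuracy-plus-resource loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
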