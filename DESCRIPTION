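Package: lindynet
Title: Exact Learning Dynamics of Two-Layer Linear Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form solutions for the gradient-flow learning dynamics of
    two-layer linear networks trained from structured (possibly large)
    initialisations, based on a generalised matrix-Riccati solution. Provides
    the stable general solution for equal and unequal input/output dimensions,
    the aligned-initialisation and 2x2 special cases, a shallow-network closed
    form, and derived observables: training loss, hidden-layer representational
    similarity matrices, the finite-width neural tangent kernel, and
    catastrophic-forgetting losses for continual learning. A full-batch
    gradient-descent simulator (linear, tanh and ReLU) serves as a numerical
    verification oracle, and experiment presets reproduce the qualitative
    phenomenology: rich versus lazy regimes, decoupling/alignment dynamics,
    continual learning, reversal learning and revision of structured knowledge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
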