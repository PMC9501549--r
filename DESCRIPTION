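Package: camnet
Title: Calcium-Calmodulin Competitive Binding Networks in Synaptic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic mass-action modelling of the postsynaptic
    Ca2+/calmodulin signalling network that controls bidirectional synaptic
    plasticity. Couples a nine-state Ca2+-calmodulin binding model (independent
    N- and C-lobes with tense/relaxed cooperativity) to a CaMKII-PP1 reaction
    network with cAMP production and hydrolysis, a PKA feedback loop, and
    inhibitor-1 regulation of PP1. Provides exponentially decaying calcium
    pulse-train stimuli (low-frequency, 10 Hz, theta-burst and 100 Hz
    protocols), a Hill-equation reduction of PKA activation, knockout
    experiments (T286A, PP1, PDE1), and a global sensitivity analysis pipeline
    based on Latin hypercube sampling, monotonicity screening, partial rank
    correlation coefficients and Kolmogorov-Smirnov regionalised sensitivity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    lhs,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
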