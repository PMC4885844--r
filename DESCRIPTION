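Package: dualHebb
Title: Dual Hebbian Weight and Wiring Plasticity in a Probabilistic
    Inference Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a two-layer rate network that
    infers a discrete hidden state from noisy exponential-family (Gaussian or
    Poisson) population input. Implements softmax winner-take-all output
    dynamics, five static strategies for encoding tuning in synaptic weights
    and/or connection probabilities (weight, connectivity, dual, cut-off,
    random coding), Hebbian weight plasticity with a homeostatic term, dual
    Hebbian wiring plasticity with detailed-balance spine creation and
    elimination, and an approximated spine-size-driven wiring rule. Evaluation
    tools include bootstrap decoding accuracy, transfer entropy, model error,
    KL-divergence connectivity optimality and per-connection information gain,
    closed-form membrane-potential statistics with analytic accuracy, and the
    information capacity of binary connections versus graded weights.
    Experiment drivers reproduce dynamic-environment training and
    motor-learning spine-turnover protocols with survival statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
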