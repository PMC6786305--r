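Package: sporenet
Title: Reward-Driven Synaptic Sampling in Closed-Loop Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reward-modulated synaptic-sampling plasticity (SPORE) in
    stochastic spiking networks closed in a loop with simulated visuomotor
    environments. Provides the synapse model (post-synaptic-potential trace,
    eligibility trace, reward-gradient estimate, parameter stochastic
    differential equation with exponential weight projection and learning-rate
    annealing), point-process neurons, an event-camera (DVS) simulation with
    address-event encoding, two environments (target reaching with
    population-vector velocity decoding, lane following with ratio-based
    discrete steering), a deterministic closed-loop experiment runner with a
    compiled fast path, and the analysis metrics used to study learning
    dynamics and synapse sparsification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
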