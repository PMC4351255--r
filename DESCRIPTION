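Package: augmentrl
Title: Attention-Gated Memory Tagging Networks for Trial-and-Error
    Learning of Working Memory Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates three-layer neural networks that learn action values
    by SARSA(lambda) implemented with biologically local synaptic tags and
    traces, gated by attentional feedback from the selected action and a
    globally broadcast reward-prediction error (the AuGMEnT learning
    scheme).  Includes discrete-time simulators for four classic primate
    working-memory experiments (memory saccade/antisaccade, delayed
    match-to-category, probabilistic evidence classification, and
    vibrotactile frequency comparison), training protocols with shaping
    rewards and convergence criteria, parameter and network-size sweeps,
    and analyses of the learned representations (principal components,
    representational similarity, category tuning, evidence-integration
    weights, and two-frequency regression with psychometric fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
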