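Package: fespike
Title: First-Error Supervised Learning for Spiking Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and supervised training of current-based leaky
    integrate-and-fire neurons that learn to reproduce precisely timed
    target spike trains. Implements the first-error learning rule, which
    adjusts synaptic weights once per trial at the earliest wrong output
    spike time (a stray spike, a duplicate spike inside a tolerance
    window, or a missed window), together with the correlation-based
    spike-train similarity metric, homogeneous-Poisson and jitter-noise
    generators, template-matching classification of spatiotemporal spike
    patterns, and a dynamic-target population decoding strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
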