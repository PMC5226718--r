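Package: wagernet
Title: Discrete Attractor Network Model of the Uncertain-Option Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a five-population spiking attractor
    network model of perceptual decision making with an opt-out ("sure")
    target, the task design known as the uncertain-option or post-decision
    wagering paradigm. Provides a conductance-based leaky integrate-and-fire
    network with AMPA, NMDA and GABA synapses and its mean-field reduction,
    fixed-point and bifurcation analysis with basin-of-attraction bisection,
    a delayed three-option stimulation protocol, a trial engine implementing
    a threshold decision rule with decision times and changes of mind, and
    the derived behavioural statistics: psychometric functions, conditional
    sure-choice maps, decision-time bimodality, the X-pattern of opt-out
    probability in correct and error trials, and reward trade-off curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
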