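Package: replaynet
Title: Predictive-Plasticity Spiking Networks that Replay Stimulus Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of Poisson spiking neurons in which
    every synapse (feedforward, recurrent excitatory, and inhibitory) follows a
    predictive plasticity rule driven by the product of a rate-prediction error
    and the presynaptic activity trace. Trained on repeated stimulus patterns,
    the networks self-organize stimulus-specific cell assemblies and, once the
    input is removed, spontaneously replay them with population rates
    proportional to the experienced stimulus probabilities. Provides the three
    network variants (mixed-sign recurrent weights, sign-constrained synapses,
    and distinct excitatory/inhibitory populations obeying Dale's law), the
    Poisson stimulation protocols (probabilistic patterns, motion-coherence
    inputs for perceptual decision making, conditioned two-subnetwork
    schedules), assembly-identification and replay metrics, and config-driven
    experiment runners with a compiled simulation core.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
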