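Package: ruleSRNN
Title: Excitatory-Inhibitory Spiking Recurrent Networks for Rule-Dependent Choice Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates and trains excitatory-inhibitory spiking recurrent neural
    networks (SRNNs) of leaky integrate-and-fire neurons on rule-dependent
    two- and four-alternative forced-choice tasks. Networks obey Dale's
    principle, carry spike-frequency adaptation on a subset of units, and are
    trained end-to-end by backpropagation through time with the SuperSpike
    fast-sigmoid surrogate gradient. Includes an analysis suite (z-scored
    PSTH rule tuning, peak-to-noise ratio, sequentiality index,
    principal-component trajectories and kinetic energy, spike-train
    correlograms, beta-rhythm detection, local-field-potential proxy,
    population decoding) and test-time perturbation experiments (rule-cue
    mixtures, delay elongation, weight sparsification, E/I block scaling,
    noise and distractor sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
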