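Package: burstclique
Title: Spiking Network Model of Developing Circuits with Driver-Cell Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Event-driven simulation of excitatory/inhibitory leaky
    integrate-and-fire networks with Tsodyks-Uziel-Markram short-term
    synaptic depression and facilitation, modelling the spontaneous
    population bursts (giant depolarizing potentials) of developing
    cortical circuits. Provides generators for network realizations with
    an excitability-connectivity anti-correlation, detection of population
    and aborted bursts, directed functional connectivity from spike-time
    cross-correlation, single-neuron deletion and stimulation protocols,
    driver-cell classification (functional hubs and low-functionally
    connected drivers), functional-clique and burst-route extraction, and
    monitoring of synaptic resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'burstclique-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'netgen.R'
    'dynamics.R'
    'bursts.R'
    'funconn.R'
    'perturb.R'
    'fixtures.R'
    'io.R'
    'pipeline.R'
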