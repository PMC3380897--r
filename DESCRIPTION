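Package: thetagamma
Title: Theta-Nested Gamma Oscillations in a Spiking Network with
    Dual-Kinetics GABAergic Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a three-population leaky integrate-and-fire network
    (excitatory pyramidal cells plus kinetically fast and slow inhibitory
    interneurons, coupled through AMPA, NMDA, GABA-A fast and GABA-A slow
    synapses) that generates gamma oscillations nested on a theta rhythm.
    Provides the matching analysis stack: mean-membrane-potential local
    field potential, Morlet wavelet time-frequency spectra, band-averaged
    amplitudes, Hilbert-phase extraction, across-neuron theta-phase
    variation, Kullback-Leibler phase-amplitude coupling coherence
    (comodulograms), and counting of gamma subcycles nested per theta
    cycle.  Includes scripted parameter sweeps, learning-stage scenarios,
    and a stimulus-strength capacity protocol relating maximal theta power
    to the number of nested gamma subcycles, as well as a synthetic
    phase-amplitude-coupled signal generator for testing the analysis
    stack independently of the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
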