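Package: spikesim
Title: Spiking-Neuron Teaching Simulator and Neural Coding Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Software re-creation of a microcontroller-based teaching neuron:
    an Izhikevich spiking-neuron simulator with the device's input channels
    (adapting photoreceptor, two exponential current synapses, membrane
    noise, static current), an on-board stimulus generator (square pulses
    and binary noise), multi-unit network wiring over digital spike lines,
    and CSV recording logs. Ships the accompanying analysis toolkit used in
    classroom experiments: spike detection, stimulus-aligned rasters and
    averages, amplitude tuning curves, phase locking (vector strength),
    stochastic-resonance characterisation, and linear-filter estimation by
    reverse correlation (spike-triggered and subthreshold averages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
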