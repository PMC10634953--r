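Package: prebotc
Title: Conductance-Based Simulation of preBotzinger Complex Bursting and
    Rhythm Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hodgkin-Huxley style simulation of the inspiratory
    rhythm-generating circuit of the preBotzinger Complex.  Single
    neurons carry a persistent sodium current (I_NaP) that supports
    conditional intrinsic bursting, plus two high-threshold currents
    (I_SPK, I_AHP) that tune spike height and afterhyperpolarization
    without changing subthreshold excitability.  Neurons are embedded in
    a sparsely connected excitatory network with short-term synaptic
    depression.  The package provides a fast fixed-step Euler engine
    (Rcpp), heterogeneous population and connectome sampling, activity
    classification (silent, bursting, tonic), burst-capability mapping
    over conductance space, population rhythm metrics, and protocol
    drivers for spike-shape sweeps, persistent-sodium block, hypoxia,
    developmental conductance scaling, extracellular potassium, and
    temperature manipulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
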