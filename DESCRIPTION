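Package: cleftsim
Title: Monte Carlo Simulation of Glutamate Release and Receptor Activation
    at Small Central Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A particle-based Monte Carlo model of the typical small central
    excitatory synapse: quantal glutamate release into a flat cylindrical
    cleft, Brownian diffusion of individually tracked transmitter molecules
    inside and outside the cleft, and hybrid concentration-driven activation
    of AMPA- and NMDA-receptor pools described by multi-state Markov kinetic
    schemes. Includes a parametric-sweep engine for studying how receptor
    number, surface density and nanoscale clustering on the postsynaptic
    density shape the peak synaptic current, including long-term potentiation
    scenarios based on receptor insertion versus receptor crowding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
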