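Package: polysnn
Title: Event-Driven Simulation of Reconfigurable Polychronous Spiking
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Storage and recall of spatio-temporal spike patterns in a
    reconfigurable polychronous spiking neural network with programmable
    and adaptable axonal delays.  Provides k-of-n constant-weight AER
    (address-event representation) codebooks with a behavioural model of an
    asynchronous bus and its three-step synchronisation sampler;
    coincidence-detector neuron backends (digital timer model and a
    behavioural leaky integrate-and-fire model) with a multiplexed
    virtual-neuron controller; axon modules with delay programming, spike
    -timing-dependent delay plasticity (three update strategies) and an
    analog-imperfection model; an event-driven network engine for training
    and recall; and synthetic pattern/noise generators with recall scoring
    and capacity, size and noise sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
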