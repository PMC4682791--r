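Package: lfpproxy
Title: Local Field Potential Proxies for Leaky Integrate-and-Fire Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid simulation scheme for predicting extracellular local field
    potentials (LFPs) from point-neuron network models. Simulates a recurrent
    leaky integrate-and-fire (LIF) network with current-based bi-exponential
    synapses, replays the same synaptic events into a population of passive
    multicompartment neuron models with algorithmically grown dendritic
    morphologies, computes the ground-truth LFP with the line-source
    approximation in a homogeneous resistive medium, and evaluates candidate
    LFP proxies built from the point-network variables (firing rate, membrane
    potential, synaptic currents, and delayed weighted sums of AMPA and GABA
    currents) by cross-correlation delay search, fraction of variance
    explained, and Bayesian information criterion model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
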