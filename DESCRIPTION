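Package: bgnetsim
Title: Conductance-Based Cortico-Basal-Ganglia-Thalamic Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Biophysical simulation of the cortico-basal-ganglia-thalamic
    circuit with a multi-compartment medium spiny neuron (MSN). Implements
    conductance-based Hodgkin-Huxley models for thalamic, subthalamic,
    pallidal, pyramidal, and dopaminergic cells, a 121-compartment stylized
    MSN with removable dendritic spines and dendrite sections, two-state
    (dual-exponential) AMPA/NMDA/GABA synapses, a memristive
    electromagnetically driven cortical neuron, and a fixed-step network
    integration engine. Provides the thalamic relay error index (EI),
    lesion and dopamine-depletion sweep drivers for studying how striatal
    morphological changes modulate thalamic signal fidelity in the
    parkinsonian state, and ggplot2 visualisation of traces and sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr,
    rmarkdown,
    readr,
    withr
Config/testthat/edition: 3
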