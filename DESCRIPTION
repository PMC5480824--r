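Package: beealt
Title: Spiking Network Simulator of the Honeybee Lateral Antennal Lobe Tract
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates olfactory learning in the honeybee lateral antennal
    lobe tract (l-ALT). Synthetic odours drive Hill-affinity adaptive
    exponential integrate-and-fire receptor neurons; a glomerular antennal
    lobe network of conductance-based leaky integrate-and-fire projection and
    local neurons, with symmetric inhibitory spike-timing-dependent
    plasticity and a global inhibitory feedback neuron, decorrelates the
    odour code; octopamine-modulated STDP onto a single lateral horn decision
    neuron supports absolute and differential conditioning, generalization,
    and positive (but not negative) patterning. Includes protocol drivers,
    population-coding metrics (entropy reduction, multi-information, angular
    distance, Treves-Rolls sparseness), and tidy result containers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
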