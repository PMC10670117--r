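Package: ca3gamma
Title: Hippocampal CA3 Microcircuit Simulation and Gamma-Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Biophysical simulation of a theta-paced hippocampal CA3
    microcircuit (multicompartment Hodgkin-Huxley pyramidal cells with OLM
    and basket interneurons, double-exponential conductance synapses, random
    wiring by convergence numbers, Poisson background drives and a
    medial-septum pacemaker) together with the analysis chain used to study
    sustained post-ketamine gamma-power changes: local field potential and
    pooled-raster Welch spectra, 30-100 Hz band power, relative gamma change
    under multiplicative AMPA-conductance scaling of recurrent versus
    external pyramidal synapses, scaling-grid and synaptic-delay-sweep
    experiments, and linear regression plus bootstrap causal mediation
    analysis of the resulting condition tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
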