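Package: thalamoburst
Title: Burst-Dependent Thalamocortical Ring Network Simulations of
    Perceptual Awareness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a spiking thalamocortical network in which dual-compartment
    layer 5 pyramidal-tract neurons switch from regular spiking to bursting when
    calcium plateau potentials in the apical dendrite coincide with somatic drive,
    with soma-dendrite coupling gated by diffuse-projecting matrix thalamus.
    Provides the single-cell and synaptic dynamics (Izhikevich quadratic
    integrate-and-fire somas, a nonlinear apical compartment, conductance-based
    AMPA/NMDA/GABA-A synapses on an orientation ring), a fast compiled
    integrator, turn-key tactile threshold-detection and visual-rivalry
    protocols with simulated optogenetic and pharmacological perturbations, and
    an analysis stack: closed-form saddle-node bifurcation geometry of the
    apical compartment, psychometric and neurometric detection readouts,
    dominance-period statistics with Gamma/lognormal/normal fits, and
    switch-triggered population summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
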