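Package: mbggn
Title: Passive-Cable and Network Model of the Locust Mushroom Body Giant
    GABAergic Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Biophysical simulation of the locust mushroom-body olfactory
    circuit centered on the giant GABAergic neuron (GGN). Provides SWC
    morphology input/output, a seeded synthetic GGN-like morphology
    generator, electrical compartmentalization and a passive branched-cable
    solver (steady-state and implicit transient), Hodgkin-Huxley-type
    Kenyon cell and Izhikevich regular-spiking point-neuron models, graded
    and spike-triggered synapse models with lognormal weight sampling,
    structured projection-neuron spike-train synthesis, assembly and
    co-simulation of the full PN-KC-GGN-IG feedback network, scripted
    simulation experiments (voltage-clamp attenuation, distributed synaptic
    drive, resistivity sweeps, Kenyon-cell dynamic range, network
    heterogeneity, high-rate-cell ablation, IG wiring variants), and
    spike and voltage analysis utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    signal,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
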