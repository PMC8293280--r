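Package: kv4pace
Title: A-Type Potassium Currents and Pacemaking in Dopaminergic Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multicompartment conductance-based modelling of substantia nigra
    pars compacta dopaminergic neuron pacemaking and postinhibitory rebound,
    focused on the A-type (Kv4-mediated) potassium current. Provides
    Hodgkin-Huxley channel kinetics with coupled I_A/I_H voltage dependence,
    stylized morphology generation with SWC input/output and d_lambda
    discretization, an implicit branched-cable integrator with calcium
    dynamics, current- and voltage-clamp feature extraction (interspike
    intervals, rebound delay, action-potential waveform, Boltzmann
    inactivation fits, mono-exponential decay fits, charge integrals), a
    biophysical parameter-database sweep with dimensional stacking, the
    associated correlation / best-subset regression / Fisher exact
    statistical procedures, and synthetic-data generators for per-neuron
    populations, voltage-clamp trace families and count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
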