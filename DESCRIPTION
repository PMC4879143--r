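Package: nocithresh
Title: Hazard-Model Simulation of Nociceptive Detection Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of a hazard model of A-delta-fiber-mediated
    detection of intra-epidermal electrocutaneous pulse trains. Detection is
    modelled as the first spike of a non-homogeneous Poisson process whose
    rate follows the postsynaptic potential of a dorsal-horn neuron driven by
    exponential synaptic currents. The package computes psychometric
    functions and 50-percent detection thresholds numerically, provides the
    closed-form threshold theory for double-pulse stimuli in the fast-synapse
    and steep-activation limits (including the interpulse-interval
    monotonicity condition), maps multiplicative perturbations of physical
    quantities onto the lumped model parameters for single-parameter sweeps,
    runs a five-day topical-capsaicin neuroplasticity scenario with ablation
    variants, and generates synthetic Bernoulli detection data for
    threshold-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
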