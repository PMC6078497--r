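Package: gridperturb
Title: Perturbation-Based Probes of Grid-Cell Circuit Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for discriminating grid-cell
    circuit mechanisms with global perturbations. Builds 1D continuous
    attractor networks with aperiodic, partially periodic and fully periodic
    recurrent connectivity, simulates them with linear-nonlinear-Poisson or
    cortical Hodgkin-Huxley dynamics under inhibitory-gain, time-constant
    and temperature (Q10) perturbations, and analyses the outcome via spatial
    tuning curves, population-pattern spectra and the distribution of
    relative phase shifts (DRPS), including stretch-factor inference, peak
    counting, periodicity scores, bootstrap phase uncertainty and a
    decision-tree classifier of circuit architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
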