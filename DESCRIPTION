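Package: hybridspike
Title: Bifurcation and Chaos Analysis for Hybrid Spiking Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and nonlinear-dynamics analysis of a planar hybrid
    spiking neuron model: a FitzHugh-Nagumo-type membrane equation coupled to
    a sigmoidal recovery nullcline, with a discontinuous after-spike resetting
    rule (v -> v_r, u -> u + d) applied when the membrane potential reaches a
    spike-detection threshold. Provides event-located hybrid integration,
    equilibrium and eigenvalue analysis with saddle-node and Hopf bifurcation
    location, Lyapunov spectra for the piecewise-smooth flow via saltation
    matrices and Gram-Schmidt renormalisation, Poincare return maps on the
    spike-threshold section, characteristic multipliers of periodic orbits
    from the variational monodromy, continuation of period-doubling and
    tangent bifurcations in the reset voltage, bifurcation diagrams, and
    interspike-interval return maps. Results are returned as tibbles with
    ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rlang,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    patchwork
Config/testthat/edition: 3
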