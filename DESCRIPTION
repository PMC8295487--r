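Package: ddnf
Title: Discrete Dynamic Neural Fields: Simulation and Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fixed-point stability analysis of discrete dynamic
    neural fields (DDNFs): multilayer lattice dynamical systems obtained from
    the Amari neural field equation by a nearly exact discretization scheme.
    Provides Mexican-hat (difference-of-Gaussians, Laplacian, hyperbolic
    tangent) lateral connectivity kernels, sigmoid and Heaviside pulse-emission
    functions, the per-step field update and trajectory simulator, a Mann-type
    averaged fixed-point iteration with contraction diagnostics, Jacobian /
    super-adjacency assembly with spectral-radius classification, closed-form
    eigenvalues for single-neuron multilayer chains, Molinari transfer-matrix
    determinants for open and closed chains, two-layer stability criteria, and
    config-driven reproduction of the reference simulation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
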