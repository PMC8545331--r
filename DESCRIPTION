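Package: odesens
Title: Simulation and Sensitivity Analysis for ODE Models of Biochemical
    Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imports SBML reaction networks as symbolic ODE models,
    derives all first-order partial derivatives symbolically once, and
    assembles total derivatives at runtime by sparse matrix products.
    Provides stiff (BDF) and nonstiff (Adams) simulation with analytic
    Jacobians, steady-state solving by damped Newton with a simulation
    fallback, and parameter sensitivities by the forward, adjoint and
    steady-state methods. Evaluates PEtab parameter-estimation problems
    (negative log-likelihood and its gradient) with pre-equilibration
    and pre-simulation support, plus a fixture-model catalogue and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
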