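Package: opetri
Title: Compositional Epidemic Modelling with Open Petri Nets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for specifying compartmental epidemic models by
    composition rather than monolithically. Provides whole-grain Petri
    nets (species, transitions and multiplicity-carrying input/output
    arcs), open Petri nets that expose places through an interface, and
    undirected wiring diagrams as a composition syntax with hierarchical
    substitution. Semantics include mass-action ordinary differential
    equations, exact stochastic simulation by the Gillespie direct
    method, and general open ODE/DDE dynamical systems (resource
    sharers) that compose by identifying shared variables and summing
    their rates of change. Typed Petri nets over a type-system net
    support model checking and stratification as a pullback, so a
    disease model can be replicated across quarantine, age or spatial
    strata automatically. A calibration layer fits transition rates to
    trajectory observations and computes finite-difference sensitivities
    of outcome functionals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
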