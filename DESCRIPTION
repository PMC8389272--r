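Package: rxnsim
Title: Multi-Layered Biochemical Reaction Network Modelling, Simulation and
    Parameter Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Build multi-layered biochemical reaction schemes in which the
    same reactant (ATP, NADH, ...) appears in many places via shortcut
    references carrying their own per-edge stoichiometric coefficients;
    automatically derive the mass balance ordinary differential equations;
    integrate them with a variable-order stiff (Gear/BDF) solver supporting
    constant pools, assignment rules and discrete events with root-localised
    triggers; estimate kinetic parameters from observed time courses by a
    modified Powell conjugate-direction method, a real-coded genetic
    algorithm, or their hybrid; and exchange models with SBML Level 3
    Version 1 Core. Ships programmatic fixtures (linear reaction chains, an
    ATP/ADP stoichiometry toy, a two-organism butanol pathway, rule/event
    toys, random schemes) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
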