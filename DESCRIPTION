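Package: gatkit
Title: Kinetic Analysis of Electrogenic Neurotransmitter Transporter Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for voltage-clamp recordings of electrogenic
    solute-carrier transporters expressed in Xenopus oocytes or mammalian
    cells: pre-steady-state charge movement (blocker subtraction, single-
    exponential relaxation fitting, charge integration, Boltzmann Q-V fitting
    and unidirectional rate constants), Hill/logistic dose-response kinetics
    with transport efficiency, two-substrate competition grids with biphasic
    (dual-effect) characterization, and superfusion radiotracer efflux
    quantification. Includes a forward simulator of voltage-step sweeps,
    dose-response tables, competition grids and efflux time courses with known
    ground truth, so every analysis stage is verifiable by parameter recovery,
    plus canonical CSV/JSON formats and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    MASS,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
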