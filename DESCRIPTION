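Package: cytoclamp
Title: Equivalent-Circuit Simulation and Current-Feedback Analysis of
    Cell Cytoplasmic Microinjection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation of whole-cell voltage-clamp recordings
    during the cytoplasmic microinjection of small adherent cells, built on
    an electric equivalent model of the cell-pipette system: Nernst
    equilibrium potentials and a multi-ion membrane battery computed from
    salt recipes, a two-node RC circuit with seal, access and pipette
    elements, Boltzmann-gated potassium and sodium channel branches, and an
    injection battery whose closure produces the permanent holding-current
    drop that signals a successful injection. The analysis layer estimates
    pipette and seal resistances from test pulses, detects injection current
    drops against a success threshold, classifies post-injection cell
    viability from step-family ion-channel responses, and runs the
    threshold-based injection control loop. A seeded synthetic-experiment
    generator produces annotated traces for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
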