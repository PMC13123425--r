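Package: forcespec
Title: Single-Molecule Force Spectroscopy, Binding Titration, and
    Enzyme Kinetics Analysis for Mechanosensitive Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse optical-tweezer pulling experiments on
    force-sensitive protein domains such as the von Willebrand factor A2
    domain: worm-like chain (Marko-Siggia) elasticity fitting, Bell-Evans /
    Evans-Ritchie dynamic force spectroscopy, kinetic Monte-Carlo simulation
    of constant-loading-rate pulling with one or more sequential unfolding
    transitions, unfolding-event detection and rupture-force histograms, and
    prediction of the force at which two unfolding-rate curves cross.
    Companion modules fit Hill-model binding titrations (microscale
    thermophoresis style serial dilutions) and quantify enzymatic initial
    rates against a standard curve, with seeded simulators for every data
    type so that the full analysis pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
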