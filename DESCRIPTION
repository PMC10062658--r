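Package: pthpulse
Title: Two-State PTH1R Receptor Dynamics, Pulsatile Secretion Patterns and
    Dose-Pattern Optimisation
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates parathyroid hormone (PTH) binding to its type 1
    receptor (PTH1R) with a linear four-state (two-conformation) receptor
    model under pulsatile square-wave and subcutaneous-injection
    pharmacokinetic stimuli.  Scaled receptor activity is summarised by a
    cellular-responsiveness functional built on exact sensory adaptation,
    and AUC-constrained optimisation problems recover glandular secretion
    patterns and injection dosing regimens that maximise or target a given
    responsiveness.  Ships a registry of healthy and disease-state
    secretion scenarios (osteoporosis variants, hyperparathyroidism,
    calcium-clamp states) together with a one-compartment subcutaneous
    pharmacokinetic preset for PTH(1-34).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
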