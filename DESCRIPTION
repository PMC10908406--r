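Package: hemowave
Title: Closed-Loop One-Dimensional Pulse Wave Modelling of Heart-Aorta-Brain Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop pulse wave model of the circulation coupling
    one-dimensional nonlinear vessel segments (elastic tube law, junction
    continuity of total pressure and mass) to a zero-dimensional four-chamber
    time-varying elastance heart with valves and to three-element Windkessel
    vascular beds.  Includes a hemodynamic analysis layer (pulsatile power
    decomposition, wave intensity and wave power, wave separation and
    reflection index, carotid pulsatility index, cerebral blood flow) and an
    experiment driver for contractility x heart-rate x aortic-stiffness
    sweeps with cardiac output fixed through the Frank-Starling mechanism.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    signal
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
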