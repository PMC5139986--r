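Package: fnirsim
Title: Simulating Systemic and Extracerebral Confounds in fNIRS Haemoglobin Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A lumped-parameter physiological simulator of the cerebral and
    extracerebral (scalp) contributions to functional near-infrared spectroscopy
    (fNIRS) haemoglobin signals. A regulated cerebral compartment couples blood
    flow (autoregulation, CO2 and O2 reactivity, metabolic demand) to a
    three-reaction model of the terminal mitochondrial electron transport chain;
    an independent Windkessel scalp compartment converts arterial pressure or
    laser-Doppler flux into superficial volume changes. The package generates
    step and multi-frequency input protocols, searches for systemic input
    combinations that mimic (false positive) or mask (false negative) functional
    activation, classifies steady-state response surfaces, and attributes
    measured signals between compartments using cross-correlation, dynamic time
    warping and non-negative weighted fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
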