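Package: headstage
Title: Virtual Opto-Electrochemical Sensing Headstage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software "virtual instrument" modelling a miniaturized
    multisensor headstage for monitoring cultured dopaminergic neurons:
    a square-wave digital lock-in impedance analyzer with a relative-impedance
    cell-growth statistic, a three-electrode potentiostat signal chain for
    cyclic voltammetry and constant-potential amperometry, and an optical
    stimulator model for channelrhodopsin activation. Includes simulators of
    the electrode/cell systems the hardware measures (constant-phase-element
    Randles circuits with a cell-coverage mechanism, 1-D diffusion cyclic
    voltammetry of reversible redox couples, stimulus-locked exocytosis spike
    trains with vesicle depletion), Savitzky-Golay filtering and spike
    detection, and CSV/YAML interfaces, so every stage is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
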