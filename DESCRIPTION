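Package: pumpfeed
Title: Feed-Profile Compilation and Closed-Loop Simulation for Programmable Syringe Pumps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing substrate-dosing strategies on multi-channel,
    gear-reduced syringe pumps and verifying them in silico. Converts desired
    bioprocess outcomes (a set specific growth rate, a chromatography gradient,
    a constant droplet flow) into motor-rotation schedules via closed-form
    integration of piecewise feed profiles; simulates the discrete
    setpoint-tracking motor controller and the fed bacterial culture (substrate
    mass balance with Monod uptake); and analyses resulting growth and yield
    data, including the decomposition of substrate demand into growth and
    heterologous plasmid-burden components. A synthetic-data module emulates
    the measurement modalities (optical density series, gravimetric dosing
    traces, yield datasets, bead-size samples) for fully reproducible testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
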