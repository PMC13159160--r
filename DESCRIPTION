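Package: sonotrace
Title: Trace-Level Analysis of Ultrasound Neuromodulation in Two-Photon
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying ultrasound-sensitive neurons in
    two-photon calcium imaging recordings of focused-ultrasound
    neuromodulation experiments. Implements the trace-level pipeline
    (background subtraction, frame averaging, peri-stimulus epoching,
    deltaF/F, baseline z-scoring, threshold-based excited-trial detection
    and response-rate classification into ultrasound-sensitive and
    weakly-responding neurons, with bidirectional modulation subgrouping of
    visual responders), the ultrasound stimulus-schedule and acoustic
    exposure computations (pulse trains, duty cycle, mechanical index,
    Isppa, Ispta), a Rayleigh-Sommerfeld annular-piston field model with
    -6 dB beamwidth extraction, and a synthetic-trace generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
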