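Package: acsprobe
Title: Multimodal Sensor Pipeline for Acute Compartment Syndrome Monitoring
Version: 0.1.0
Authors@R: person("ACS", "Probe Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Signal-processing pipeline for a multimodal intracompartmental
    probe that measures pressure, tissue oxygen saturation (StO2) and local
    blood flow at a common site inside an osteofascial muscle compartment.
    Implements thermal-anemometry flow inversion with a Bessel-integral shape
    factor, reflection-mode StO2 via the modified Beer-Lambert law with AC/DC
    photoplethysmogram separation, temperature-compensated pressure
    calibration, and the perfusion-pressure (delta-P) fasciotomy decision
    rule, together with a seeded synthetic episode generator that emulates a
    stepped balloon-inflation compartment-syndrome experiment so the whole
    chain is testable against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
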