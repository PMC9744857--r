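Package: sonoline
Title: Electro-Acoustic Transmission-Line Simulation of Ultrasonic Vagus
    Nerve Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: One-dimensional traveling-wave simulation of ultrasonic
    neurostimulation through layered and branched tissue networks, using the
    electro-acoustic transmission-line analogy (pressure as voltage, tissue
    layers as ideal lossless lines). Builds the cervical vagus nerve model
    and the site-focused splenic stimulation model, synthesises A-scan
    voltage traces with impedance-mismatch scattering at branch points,
    extracts first-peak arrival times and delivered voltages, and assembles
    per-terminal dosimetry reports (mechanical pressure, spatial-peak
    temporal-average intensity, attenuation in dB) with safety
    classification against action-potential, FDA therapeutic and
    thermal-burn intensity thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
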