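Package: ucachar
Title: Acoustic Characterization of Ultrasound Contrast Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for in-vitro acoustic characterization of
    ultrasound contrast agents (microbubbles and antibubbles): averaged
    amplitude spectra and harmonic side-scatter statistics with replicate
    aggregation and significance testing, through-transmission and echo-mode
    attenuation estimation by the insertion-loss method, linear backscatter
    fraction, contrast-specific pulse-inversion/amplitude-modulation frame
    combination with time-intensity-curve bolus analysis under a triangular
    indicator-dilution model, mechanical-index and dilution arithmetic, and a
    seeded synthetic acquisition generator providing ground truth for every
    estimator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
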