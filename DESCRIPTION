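Package: oxitone
Title: Skin-Tone-Calibrated Smartphone Pulse Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-processing pipeline for dual-wavelength (red/blue)
    transmission photoplethysmography captured with a smartphone screen and
    camera. Reads per-frame mean-RGB logs, demultiplexes alternating
    red/blue illumination into channel signals, filters them (Butterworth
    bandpass plus Savitzky-Golay smoothing), extracts windowed AC/DC
    features and the ratio of ratios, estimates heart rate, and maps the
    ratio to peripheral blood oxygen saturation (SpO2) with linear or
    quadratic models under k-fold cross-validation. Classifies skin tone
    from images against a six-patch Fitzpatrick reference strip and applies
    tone-normalization coefficients that correct the wavelength-dependent
    attenuation bias of darker skin. Ships a Beer-Lambert forward simulator
    that generates frame logs with known SpO2 and heart-rate ground truth,
    plus one-way ANOVA utilities for quantifying skin-tone bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
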