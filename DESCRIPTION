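Package: specloc
Title: Bayesian Spectral-Cue Model of Sound Elevation Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative Bayesian observer model of human sound-source
    elevation perception from pinna-related spectral cues. Provides a
    parameterized generator of canonical head-related transfer functions
    (HRTFs) with an elevation-dependent spectral notch, construction of
    spectral-contrast stimuli defined by notch-band and outer-band
    intensities, a localization model (spectral weighting, template
    cross-correlation, rectified likelihood, spatial prior, MAP or sampling
    decision), a virtual psychophysics experiment with a sensory noise
    model, and stimulus-response regression analysis minimizing mean
    absolute error (gain, bias, correlation, precision).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
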