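Package: dotdecode
Title: Template-Matching Decoding of Naturalistic Stimuli from
    High-Density Diffuse Optical Tomography Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for decoding naturalistic
    movie-viewing stimuli from high-density diffuse optical tomography
    (HD-DOT) recordings.  Provides a seeded synthetic-session generator
    (optode grids, analytic sensitivity matrices, hemodynamic movie
    responses with superficial, drift, pulse and white noise), the standard
    HD-DOT channel-cleaning chain (noisy-channel rejection, band-pass
    filtering, superficial signal regression, downsampling), spatially
    variant Tikhonov image reconstruction with flat-field field-of-view
    estimation and two-wavelength spectral decomposition to hemoglobin,
    localizer-based region-of-interest construction, spatiotemporal
    template-matching classification by maximum Pearson correlation, and
    statistical evaluation of decoding performance (confusion matrices,
    exact binomial tests against chance, Cohen's d, parameter sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    graphics,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
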