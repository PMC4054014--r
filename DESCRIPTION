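Package: oriband
Title: Orientation-Bandwidth Noise Detection: Ideal Observers, Staircases,
    and Power-Spectrum Classification Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of noise-in-noise detection psychophysics
    for orientation summation. Synthesizes orientation-band-limited Gaussian
    noise targets embedded in white-noise masks, simulates ideal and
    template-based observers in a two-interval forced-choice task driven by
    transformed up-down staircases, fits cumulative-normal psychometric
    functions and threshold-versus-bandwidth power laws with bootstrap
    confidence intervals, computes absolute efficiency against the ideal
    observer, and estimates orientation channels from power-spectrum
    classification images fitted with constrained difference-of-Gaussians
    tuning functions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
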