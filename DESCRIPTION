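Package: nirsim
Title: Forward Simulation of Near-Infrared Spectra of Composite Biological Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximates near-infrared (NIR) absorbance spectra of composite
    biological samples (e.g. minced meat) from the concentrations and
    absorption-coefficient curves of their major chromophores (water, protein,
    fat).  Provides a Beer-Lambert linear-mixing model with an exponential
    absorption-to-absorbance calibration, an N-layer plate (Stokes)
    radiative-transfer model with averaged Fresnel transmissivity and
    exponential-integral diffuse plate transmission, a hyperspectral
    digital-value to reflectance/pseudoabsorbance calibration chain, and a
    chemometric evaluation suite (RMSE, ratio of performance to deviation,
    Willmott's index of agreement).  Synthetic Gaussian-band optical-constant
    generators make every step testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
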