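Package: rgcadapt
Title: Linear-Nonlinear Models of Retinal Ganglion Cell Adaptation
    Between White Noise and Naturalistic Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits constrained linear-nonlinear (LN) Poisson encoding models
    to retinal ganglion cell spike responses and quantifies how spatial
    receptive fields differ between white-noise and naturalistic-movie
    stimulation.  Provides a rank-two difference-of-Gaussians LN model and
    an unconstrained rank-one LN model trained by Adam on the Poisson
    likelihood, an out-of-domain adaptation protocol with frozen spatial
    filters, receptive-field center-size and surround-amplitude estimators
    (Gaussian parameters, post-hoc difference-of-Gaussians fits, and
    smoothing/thresholding), radially averaged spatial power spectra and
    filter transfer functions, and a whitening analysis in the spirit of
    efficient coding.  A synthetic stimulus and LN-Poisson response
    generator makes the full analysis testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    signal,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
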