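Package: woodnir
Title: Chemometric Modeling of Wood Density from Vis-NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for predicting wood density from visible/near-infrared
    reflectance spectra. Implements lifting-wavelet and classical wavelet
    denoising with a sequential wavelet-parameter search, multiplicative
    scatter correction and standard normal variate transforms, four
    wavelength-selection algorithms (UVE, CARS, SPA, IRIV), linear (PLS,
    PCR) and nonlinear (GRNN, epsilon-SVR) calibration models, and the
    metaheuristic tuners used with them: fruit-fly optimization for the
    GRNN spread, particle-swarm optimization for SVR hyperparameters, and
    Box-Behnken response-surface optimization of the swarm meta-parameters.
    A synthetic spectra generator with known band structure supports
    end-to-end validation when measured spectra are unavailable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
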