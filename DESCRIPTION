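Package: ppgmc
Title: Monte Carlo Photon Transport for Reflection-Mode Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based Monte Carlo photon transport in layered skin with
    pulsatile cylindrical blood vessels and in two-layer hemoglobin/ink
    optical phantoms, together with the photoplethysmography (PPG) analysis
    layer built on top of it: diffuse reflectance, the negative-log PPG
    waveform, the AC/DC pulse-quality ratio, and detected-weight-averaged
    mean optical pathlengths from per-medium partial pathlengths. Includes
    Henyey-Greenstein scattering, Fresnel boundary handling, Russian
    roulette, a steady-state diffusion-theory reflectance oracle, chromophore
    spectrum utilities (Beer-Lambert extraction, concentration scaling), and
    a synthetic generator for noisy diffuse-reflectance spectra of a
    seven-phantom cardiac-pulse series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
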