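Package: reflphase
Title: Phase-Function Diagnosis of Turbid Media from Light Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical modelling and inversion of light reflectance from
    forward-peaked scattering media such as biological tissue. Implements the
    improved small-angle scattering approximation (SAA) to radiative transfer
    for sub-diffusive reflectance, snake and diffusion terms for large
    source-detector separations, a two-parameter (isotropic weight and forward
    angular width) mapping of arbitrary single-scattering phase functions,
    exact Mie phase functions for sphere suspensions, a scalar Monte Carlo
    photon-transport simulator for validation, and a two-stage least-squares
    pipeline that recovers the complete optical-property set (scattering,
    absorption and backscattering coefficients, anisotropy and phase-function
    parameters) from radial or spatial-frequency reflectance profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
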