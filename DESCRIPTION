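Package: tendonoptics
Title: Orientation-Resolved Tissue Optics of Tendon
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the anisotropic optical properties of
    fibrous tissue such as tendon. Fits goniometer angular scattering scans
    with a two-lobe Henyey-Greenstein model to recover effective anisotropy,
    runs weighted-packet Monte-Carlo photon transport in slab and voxel
    geometries, inverts integrating-sphere diffuse reflectance and total
    transmittance spectra against Monte-Carlo lookup tables to recover
    water-scaled absorption and power-law reduced scattering spectra, and
    simulates fiber-delivered light transmission through centimeter-scale
    tissue volumes for photobiomodulation dosimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
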