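Package: trpes
Title: Time-Resolved Photoelectron Imaging Analysis of Excited-State
    Isomerisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-resolved photoelectron velocity-map imaging of
    molecular anions, built around the single-bond isomerisation dynamics of
    a photoactive yellow protein chromophore anion on its S1 state.  Provides
    a synthetic image-stack generator driven by a one-dimensional wavepacket
    model, polar onion peeling inversion of velocity-map images with
    Legendre-polynomial angular decomposition (anisotropy parameters beta2 and
    beta4), assembly of time/energy-resolved spectral and anisotropy maps with
    window integration and damped-oscillation/decay transient fitting under a
    Gaussian instrument response, plane-wave Dyson-orbital modelling of
    photoelectron angular distributions from Cartesian Gaussian expansions,
    and linear interpolation in internal coordinates (LIIC) with the
    photon-energy bookkeeping used to assign photoelectron features to
    critical-point geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rhdf5,
    statmod,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
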