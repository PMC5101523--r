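Package: nnmodes
Title: Nonlinear Network Models, Discrete Breathers and Vibronic Spectra for
    Pigment-Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grains protein structures (one node per residue at the
    C-alpha position, multi-node bacteriochlorophyll pigments) into an
    anharmonic elastic network with harmonic (k2) plus quartic (k4) pair
    potentials inside a distance cutoff, computes harmonic normal modes from
    the mass-weighted Hessian, integrates microcanonical anharmonic dynamics
    with a velocity-Verlet scheme to detect energy localisation and discrete
    breathers (displacement power spectra, energy Fourier peaks, participation
    ratios, displacement maps), and computes disorder-averaged vibronic linear
    absorption, linear dichroism and circular dichroism spectra for Frenkel
    exciton systems coupled to a single discrete vibrational mode. Includes
    synthetic generators (anharmonic chains, C3-symmetric toy trimers, toy PDB
    files, small exciton fixtures) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
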