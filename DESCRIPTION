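Package: phycoexciton
Title: Exciton Structure and Optical Spectra of Phycobiliprotein Antenna Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse the exciton structure of cryptophyte phycocyanin
    antenna complexes (open PC612-like and closed PC645-like architectures) from
    ensembles of pigment site energies and couplings. Builds and diagonalizes
    Frenkel exciton Hamiltonians with dipole and rotational strengths, evaluates
    spectral densities (overdamped Brownian oscillator plus discrete vibronic
    modes), lineshape functions and modified Redfield rates, and simulates
    disorder-averaged absorption, circular dichroism and fluorescence spectra
    with either a modified Redfield or a second-order matrix cumulant theory.
    Includes estimators of static disorder from nested molecular-dynamics
    ensembles, bilin tetrapyrrole torsion analysis with circular statistics,
    per-residue RMSF, protomer rotation angles, and a synthetic-data generator
    that replaces the quantum-chemistry machinery for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
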