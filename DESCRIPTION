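Package: marrowdose
Title: Active Bone Marrow S-Values for Electron-Emitting Radionuclides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Skeletal dosimetry toolkit for beta- and Auger/conversion-electron
    emitting radionuclides used in radionuclide therapy (terbium-161,
    lutetium-177, yttrium-90). Builds per-decay electron emission spectra from
    Fermi theory, convolves them with energy-gridded specific absorbed
    fraction (SAF) tables for active bone marrow targets to obtain MIRD-style
    S-values, applies skeletal-site mass averaging, spongiosa averaging and
    marrow-cellularity scaling, and includes a condensed-history Monte Carlo
    electron transport simulator for voxel-scale energy deposition studies.
    A synthetic-data generator produces self-consistent SAF libraries,
    skeletal mass tables and decay fixtures for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
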