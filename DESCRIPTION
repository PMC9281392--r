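Package: symdyn
Title: Molecular Dynamics Under Space-Group and Wallpaper-Group Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular dynamics in which the crystallographic symmetry group is
    an input. Only the asymmetric unit is integrated; all symmetry mates and
    lattice images are ghost particles whose positions are derived from the
    asymmetric unit by the group's affine operators in fractional coordinates.
    Constant-pressure sampling uses Metropolis Monte Carlo box-scaling moves
    projected onto the Bravais lattice of the group, and particles placed on
    special Wyckoff positions are held there exactly by analytic Lagrange
    multiplier constraints. Ships operator tables for all 17 wallpaper groups
    and a small set of 3D space groups, velocity-Verlet and BAOAB Langevin
    integrators, and protocol drivers for energy-conservation checks and a
    Lennard-Jones crystal-structure screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
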