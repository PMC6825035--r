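Package: fibrildeg
Title: Enzymatic Degradation and Mechanics of Collagen Fibrils
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the degradation of a single collagen fibril by
    collagenase (MMP-1-like) and gelatinase (MMP-9-like) enzymes with a
    dynamic Metropolis Monte Carlo lattice model, maps the degraded
    lattice onto a coarse-grained bead-spring representation, and runs
    reduced-scale tensile tests with a built-in molecular dynamics
    engine (full-scale structures are exported as LAMMPS data files).
    Includes post-processing statistics that connect the degradation
    pattern to fibril mechanics: degradation time courses,
    cross-sectional density maps, enzyme pause fractions and axial
    trajectories, stress-strain curves, yield point and toughness, and
    bond-length distributions with sliding/stretching classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
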