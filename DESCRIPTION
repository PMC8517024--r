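Package: cellmech
Title: Coarse-Grained Cell Mechanics Simulation and Quantitative Cell Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional coarse-grained bead-spring model of an adherent
    cell (plasma membrane, nuclear membrane, and radial actin filaments bonded
    by finitely extensible springs, interacting through Lennard-Jones and
    Weeks-Chandler-Andersen pair potentials), a Langevin molecular-dynamics
    engine, and a virtual atomic-force-microscopy (AFM) indenter for probing
    how cortical contractility (actin-membrane attraction) and cell-cell
    adhesion (membrane-membrane attraction) set cell stiffness and colony
    cohesion.  Companion quantification tools cover Hertz-Sneddon elastic
    modulus fitting of force-indentation curves, shape morphometrics
    (circularity, solidity), nearest-neighbour distance densities, AFM surface
    ruffle counting, focal-adhesion segmentation, and ratiometric FRET indices
    with bleed-through correction.  Seeded synthetic-data generators with
    stored ground truth make every analysis stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
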