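Package: chameleonics
Title: Conformational Chameleonicity and Permeability Descriptors for
    Beyond-Rule-of-5 Degraders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of conformer ensembles of flexible beyond-Rule-of-5
    molecules such as PROTAC degraders. Computes per-conformer compactness
    and polarity descriptors (radius of gyration, solvent-accessible surface
    area, solvent-accessible 3D polar surface area), detects intramolecular
    interactions (hydrogen bonds, Burgi-Dunitz n->pi* approaches, pi-stacking,
    C-H/pi contacts), clusters ensembles on pairwise heavy-atom RMSD, and
    searches for congruent conformations shared between polar- and
    nonpolar-environment ensembles. Companion calculators convert NH
    chemical-shift solvent differences into hydrogen-bond acidity
    descriptors, microsomal disappearance into scaled intrinsic clearance,
    PAMPA concentrations into apparent permeability, and dose-response
    series into DC50/Hill fits with hook-effect handling. A seeded synthetic
    data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    minpack.lm,
    deSolve,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
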