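Package: lipofold
Title: Conformation and Interfacial Location of Lipoquinones from NOE,
    Chemical-Shift and Langmuir Monolayer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for determining the solution conformation and the
    membrane-interface location of lipoquinones (ubiquinone and
    menaquinone analogs) from desk-scale spectroscopic and tensiometric
    data.  Implements NOESY cross-peak volume standardization and
    strong/medium/weak distance calibration with a continuous isolated
    spin-pair (r^-6) cross-check, idealized-geometry 3D model building
    for UQ-n/MK-n with a restrained torsion-space optimizer, dihedral
    based classification of conformers into flat-extended,
    folded-extended and U-shaped families, reverse-micelle chemical
    shift localization of a probe (organic bulk, water pool or
    interface), and Langmuir compression isotherm workup (surface
    pressure, replicate averaging, per-phospholipid area normalization,
    compression modulus, second-derivative collapse detection and
    physiological-window area expansion).  Includes seeded synthetic
    data generators for every input so the full pipeline is testable
    without instrument output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
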