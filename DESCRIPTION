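Package: restraintr
Title: Adaptive Reference-Model Restraints for Macromolecular Rebuilding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates, manages and applies adaptive ("top-out") distance and
    periodic torsion restraints that bias a working macromolecular model
    towards a reference structure while tolerating genuine differences.
    Implements a flat-bottomed generalisation of the Barron robust loss for
    interatomic distances, a renormalised von Mises-derived periodic potential
    for torsions with a tuneable fall-off, the full reference-restraint
    generation protocol (sequence pairing, iterative pseudo-rigid-body
    detection, distance and torsion restraint assignment), restraint
    classification, adjustment and release, a torsion chord score for model
    comparison, and a gradient-based relaxer that settles a model under its
    restraint network. Structures are handled as tidy atom tables with PDB
    and mmCIF input via 'bio3d'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
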