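Package: chelstab
Title: Stability Constants of Transition-Metal Amino-Acid Chelates from
    Valence Connectivity Indices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative structure-property (QSPR) modelling of the
    stability constants (log K1, log beta2) of bivalent first-row
    transition-metal chelates (Mn, Fe, Co, Ni, Cu) with the aliphatic
    alpha-amino acids glycine, alanine, valine and leucine. Builds
    vertex-weighted heavy-atom graphs of the mono- and bis-amino-acid aqua
    complexes, computes the third-order valence molecular connectivity
    index (3-chi-v) by exhaustive simple-path enumeration with Kier-Hall
    valence deltas, and fits simultaneous quadratic regression models
    normalised on the nickel complex, with leave-one-out cross-validation
    and per-metal / per-ligand diagnostic fits reflecting the
    Irving-Williams stability order.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
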