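Package: xlambig
Title: Ambiguity-Aware Cross-Linking Restraints for Homo-Oligomer Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for using chemical cross-linking mass-spectrometry (XL-MS)
    restraints in the modeling of homo-oligomeric protein complexes, where
    sequence-identical subunits make intra- vs inter-subunit assignment of a
    cross-link ambiguous. Computes Euclidean and solvent-accessible-surface
    (grid shortest-path) C-alpha distances between lysine residues, classifies
    candidate cross-links as intra-subunit, inter-subunit, ambiguous or
    non-accessible at a configurable linker threshold, simulates cross-link
    datasets and rigid-body decoy ensembles for C2-symmetric homo-dimers, and
    scores models with the MNXL (Matched and Non-accessible cross-link) score
    family, including ambiguity-, orientation-, inclusion- and symmetry-aware
    variants. Provides top-10 near-native precision evaluation of ranked decoy
    ensembles against recreated reference structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
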