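Package: capsidkit
Title: Geometry, Assembly and Mass Analysis of Prolate and Isometric Phage Capsids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quasi-equivalent lattice mathematics of icosahedral and
    five-fold prolate bacteriophage capsids (triangulation and Q numbers, capsomer
    and subunit accounting with portal substitution), explicit three-dimensional
    capsomer-lattice model construction with adjacency graphs, ring partitions,
    helical parameters and inter-capsomer dihedral angles, a stochastic simulator
    of the pentamer-species capsid size-redirection decision, intact-mass
    cleavage-site mapping for scaffolding (delta) domain boundary determination,
    SDS-PAGE apparent molecular-weight calibration, and sequence-guided rigid-body
    superposition with core RMSD reporting. Includes deterministic synthetic-data
    generators so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
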