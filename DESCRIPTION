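Package: sbmfold
Title: Coarse-Grained Structure-Based Models for Multidomain Protein Folding
    and Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and simulates coarse-grained structure-based (Go-type)
    models of multidomain proteins and protein-nucleic acid complexes, with a
    single ratio parameter controlling the relative strength of interdomain
    versus intradomain native contacts.  Provides native-contact map
    construction from PDB structures, a decomposed Hamiltonian with
    Debye-Hueckel electrostatics, Langevin dynamics, temperature
    replica exchange, umbrella sampling and well-tempered metadynamics,
    WHAM free-energy estimation, Hamiltonian reweighting across contact
    strengths, melting-curve cooperativity indices, folding-order and
    backtracking kinetics, and binding-affinity and encounter-time analyses,
    together with seed-deterministic synthetic toy systems with closed-form
    reference statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
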