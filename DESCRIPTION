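Package: rnabd
Title: Brownian Dynamics of Coarse-Grained RNA Bead-Spring Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds one-bead-per-nucleotide elastic-network models of RNA from
    secondary structure (dot-bracket or helix tables), simulates them with the
    Ermak-McCammon Brownian dynamics algorithm with or without hydrodynamic
    interaction (Rotne-Prager-Yamakawa tensor), and predicts dilute-solution
    properties: radius of gyration, translational diffusion coefficient via
    rigid-body bead-model hydrodynamics or the Einstein relation, harmonic
    rotational relaxation time, inter-arm angle statistics, and a Svedberg
    sedimentation estimate. Ships ready-made topologies for yeast tRNA-Phe
    and E. coli 5S rRNA.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
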