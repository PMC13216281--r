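Package: meaobond
Title: Chemical Bonding Analysis with Maximally Entangled Atomic Orbitals
Version: 0.1.0
Authors@R: person("meaobond", "developers", email = "meaobond@example.org",
    role = c("aut", "cre"))
Description: Quantitative chemical-bonding analysis from quantum information
    theory. Constructs atom-localized orbitals that maximize inter-atomic
    two-orbital coherence (maximally entangled atomic orbitals, MEAOs),
    groups them into two-center and multicenter bonds via mutual-information
    correlation graphs, and scores bonds by orbital entanglement: relative
    entropy of entanglement for orbital pairs and genuine multipartite
    entanglement (GME) for multicenter clusters and aromatic rings. Includes
    a self-contained minimal electronic-structure engine (Gaussian-orbital
    integrals, restricted Hartree-Fock, complete-active-space configuration
    interaction) plus intrinsic-atomic-orbital and Loewdin Hilbert-space
    partitioning, so the full pipeline runs from an XYZ geometry and a basis
    set name with no external quantum-chemistry dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
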