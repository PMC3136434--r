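Package: bindfe
Title: Post-Processing Binding Free-Energy Analysis for Receptor-Peptide Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-state and alchemical free-energy analysis of receptor-peptide
    conformer ensembles. Implements single-trajectory MM-PBSA with a
    finite-difference Poisson-Boltzmann solver and surface-area nonpolar term,
    normal-mode vibrational entropy, computational alanine and glycine scanning
    by side-chain truncation, a hybrid scheme that consumes externally supplied
    high-level gas-phase energies with power-law-scaled polar solvation and
    representative-snapshot selection, three-stage thermodynamic integration
    with soft-core potentials and Gaussian quadrature, and supporting
    trajectory analytics (hydrogen-bond occupancy, block averaging, backbone
    RMSD). A synthetic-data module generates toy receptor-hairpin complexes
    with stored ground truth so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    pracma,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
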