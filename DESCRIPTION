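Package: mdensemble
Title: Comparative Analysis of Molecular Dynamics Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing molecular dynamics conformational ensembles
    of protein complexes, built around the analyses used to contrast
    calcium-bound and calcium-free calmodulin-kinase assemblies:
    least-squares superposition and RMSD time series, Cartesian covariance
    principal component analysis with Boltzmann-inverted free-energy
    landscapes, dynamical cross-correlation matrices, persistence-contact
    residue networks with Girvan-Newman community decomposition and
    difference contact network analysis, radial distribution functions with
    ion coordination-number and coordination-mode catalogues, GROMOS-style
    ensemble clustering with representative-structure extraction, and an
    MM-GBSA interaction-energy decomposition (Coulomb, Lennard-Jones,
    pairwise-descreening generalized Born, Shrake-Rupley surface area).
    A synthetic-ensemble generator with prescribed cross-correlation
    structure, two-substate mixtures and ion solvation-shell toys provides
    ground truth for every stage without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
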