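Package: betactin
Title: Integrative Analysis of CaVbeta-Actin Complex Formation and Channel Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative structural and functional analysis of the
    interaction between voltage-gated calcium channel beta subunits (CaVbeta)
    and filamentous actin. Covers normalization and multi-engine consensus
    filtering of cross-linking mass spectrometry (XL-MS) residue-pair reports,
    accessible-interaction-space scanning of Calpha-Calpha distance restraints
    with iterative false-positive removal, CAPRI-style evaluation of
    protein-protein docking ensembles (interface and ligand RMSD metrics,
    neighbour-count clustering, restraint-violation checks, contact-frequency
    maps), consensus computational alanine scanning for interface hotspot
    ranking, whole-cell electrophysiology analysis (Boltzmann activation,
    gating-charge integration, stationary noise analysis of channel number and
    unitary conductance, bootstrap group comparison), and biophysical assays
    (two-state thermal unfolding of the spectral center of mass, F-actin
    cosedimentation bound fractions). A seeded synthetic-data module generates
    inputs with the geometric and statistical structure every stage assumes, so
    the full pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
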