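Package: atriagp
Title: Autonomic Modulation of Atrial Fibrillation Dynamics in a Left Atrial
    Simulation Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monodomain simulation of human left atrial electrophysiology with
    autonomic (ganglionated-plexus) modulation. Implements the
    Courtemanche-Ramirez-Nattel human atrial ionic model with an
    acetylcholine-activated potassium current, pulmonary-vein and
    atrial-fibrillation remodeling variants, reaction-diffusion integration on
    2D sheets and triangulated surface meshes, a parametric idealized left
    atrium with an octopus-style ganglionated-plexus/nerve acetylcholine
    field, pacing and virtual-ablation protocols, and analysis tools for
    action-potential features, early afterdepolarizations, virtual
    electrograms, complex-fractionated-electrogram cycle length, and phase
    singularity detection and tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
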