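Package: callusim
Title: Micro-Multiphysics Agent-Based Simulation of Bone Defect Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled simulation of bone regeneration after osteotomy at
    micro-CT resolution: voxel hexahedral micro-finite-element mechanics
    (density-to-modulus mapping, strain-energy density and effective strain
    with Gaussian regularisation), an implicit backward-time centred-space
    reaction-diffusion-decay solver for cytokines and oxygen with
    receptor-ligand kinetics, single-cell lattice agents with mechano- and
    cytokine-regulated migration, proliferation, differentiation, osteoid
    deposition and cluster-gated resorption, VEGF-driven sprouting
    angiogenesis, and osteoid mineralisation. Includes a synthetic
    femur-osteotomy phantom generator, an in silico gap-size study driver,
    and a time-lapsed morphometry layer (multidensity BV/TV, BFR/BRR,
    cortical metrics, ray-traced gap width, vascular volume, RMSE scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    RNifti,
    igraph,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
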