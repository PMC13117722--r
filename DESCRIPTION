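Package: vesica
Title: Coarse-Grained Spherical Liposome Construction and Membrane
    Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds whole spherical coarse-grained (MARTINI 2.x) liposomes
    of DPPC, DOPC or POPC with leaflet populations set by area-per-lipid,
    solvates the inner core and the outer box with coarse-grained water,
    and emits simulation-ready GROMACS-dialect structure (GRO), index
    (NDX), topology (TOP/ITP) and run-parameter (MDP) files with three
    separate temperature-coupling groups (inner water core, lipid bilayer,
    outside water) for portion-selective heating protocols.  Also computes
    standard analyses on coarse-grained structures and trajectories:
    molecular radial distributions by minimum inter-bead distance, vesicle
    area-per-lipid, mean-square displacement and diffusion coefficients,
    group-group nonbonded (Lennard-Jones and Coulomb) energies, tail kink
    angles, end-to-end tail distances, and spherical pore detection.  A
    synthetic-fixture module generates ground-truth trajectories (Brownian
    walks, Boltzmann-sampled lipid conformers, punched-hole vesicles) so
    every analysis can be validated without an external molecular-dynamics
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
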