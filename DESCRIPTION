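Package: solvshell
Title: Regional Solvation-Shell Dynamics and Protein Flexibility from
    Molecular Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterises solvent behaviour in the first solvation shell
    around named regions of a protein (helices, sheets, loops and
    connectors) and relates it to regional protein flexibility. Provides
    proximal radial distribution functions with first-shell cutoff
    detection, shell residence times (survival correlation and first-exit
    histogram), local diffusion coefficients from mean-square
    displacements, hydrogen-bond lifetime autocorrelation, reorientation
    times, local-viscosity and mobility descriptors with Stokes-Einstein
    and Kramers utilities, per-residue RMSF with regional integration and
    flexibility ratios, descriptor-flexibility correlation panels, and
    conformational transition rates from a coarse-grained Markov / hidden
    Markov model of a one-dimensional inter-region distance feature.
    Synthetic-trajectory generators with known ground truth (Brownian
    solvent, shell exchange, telegraph hydrogen bonds, Markov jump
    features, harmonic proteins, double-well Langevin dynamics) make every
    estimator verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
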