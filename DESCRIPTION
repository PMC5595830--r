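Package: kinflow
Title: Markov State Models and Information Flow for Receptor Activation
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kinetic analysis of molecular-dynamics trajectory ensembles of
    G protein-coupled receptor activation. Builds structural descriptor sets
    (C-alpha pair distances, sidechain contact maps, ligand contact maps),
    reduces them with time-lagged independent component analysis, discretizes
    the slow subspace into microstates and estimates reversible Markov state
    models with implied-timescale and Chapman-Kolmogorov validation, lumps
    microstates into metastable macrostates with PCCA+, classifies macrostates
    into activation regions, computes transition-path-theory committors,
    reactive fluxes, pathway decompositions and mean first-passage times,
    quantifies directed information flow between residues with
    shuffle-corrected transfer entropy and HITS hub/authority scoring, and
    encodes protein-ligand binding modes as 7-bit structural interaction
    fingerprints. A synthetic-data module generates inputs with known ground
    truth (discrete Markov chains, multi-well diffusions embedded in toy
    coordinates, directionally coupled contact processes, toy complexes) so
    every stage is testable without the original simulation data. Errors are
    estimated with a trajectory bootstrap.
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
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
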