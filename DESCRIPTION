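Package: gasflux
Title: Three-State Kinetics of Diatomic Gas Migration in Heme Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of gas-ligand (NO, CO, O2) migration through a protein
    matrix from molecular dynamics trajectories. Classifies every ligand in
    every frame into one of three states (geminate pair with the heme Fe,
    protein matrix, solvent), counts complete solvent-protein-geminate
    passage events, and derives second-order entry (k1) and first-order exit
    (k-1) diffusion rate constants together with their equilibrium constant.
    Also provides per-residue RMSF profiling with rigid-body superposition,
    global gas-protein contact descriptors, contact-based binding-pocket
    identification with occupancy and residence statistics, and synthetic
    generators (Markov state sequences, a Brownian toy shell system, and
    jittered structures) for estimator validation and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
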