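Package: EMUnet
Title: Adjacency-Matrix Elementary Metabolite Unit Decomposition and
    Isotope Labeling Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Steady-state carbon isotope labeling simulator for 13C
    metabolic flux analysis, built on an adjacency-matrix formulation of
    the Elementary Metabolite Unit (EMU) framework. Parses atom-mapped
    reaction models, builds the metabolite adjacency matrix (MAM),
    decomposes the network into size-stratified EMU adjacency matrices
    (EAMs) by breadth-first search, reduces them by lumping unimolecular
    chains and combining rotationally equivalent EMUs, and solves the
    cascaded linear EMU balances to simulate mass distribution vectors
    (MDVs) and fractional labeling (FL). Includes a brute-force
    isotopomer simulator used as an independent correctness oracle,
    random sampling of mass-balanced flux vectors, screening of
    tracer/readout combinations for 13C-tracer experiment design, and
    flux-ratio estimation from measured fractional labeling, applied to
    phosphoketolase flux in xylose catabolism.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
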