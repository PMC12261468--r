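Package: cfmdock
Title: Conditional Flow-Matching Transport of Apo Protein-Ligand Complexes to Holo States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale machinery for flow-matching generative docking:
    harmonic (graph-Laplacian) ligand priors and noised apo protein priors,
    conditional optimal-transport (CondOT) path construction with an
    endpoint-parametrized flow-matching loss, unbalanced apo-holo coupling
    filters based on TM-score and RMSD after ligand-proximity-weighted
    Kabsch superposition, a variance-diminishing ODE sampler with a plain
    Euler baseline, a small trainable equivariant endpoint field with
    confidence and affinity ranking heads, and a synthetic bead-chain
    complex generator so that every component is testable without external
    data. Structures are read and written as PDB; ligands as SMILES, SDF,
    or a plain bond-list format.
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
    ChemmineOB,
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
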