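Package: pharmnet
Title: Ligand-Based Pharmacophore Screening and Continuous Petri-Net
    Simulation of IGF-1R Signaling
Version: 0.1.0
Authors@R:
    person("pharmnet", "developers", email = "pharmnet@example.org",
           role = c("aut", "cre"))
Description: Tools for ligand-based pharmacophore modeling and virtual
    screening, together with a deterministic continuous Petri-net engine
    for signaling-network simulation.  Provides a three-feature distance
    constrained pharmacophore matcher with RMSD scoring, a Lipinski and
    drug-likeness screening cascade over SMILES/SDF libraries, rule-based
    pharmacophore feature perception with seeded conformer embedding,
    mass-action and Michaelis-Menten Petri nets with inhibitory arcs,
    packaged reconstructions of an IGF-1R/ER-alpha signaling network in
    untreated and fulvestrant-treated conditions, and synthetic-library
    generators with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
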