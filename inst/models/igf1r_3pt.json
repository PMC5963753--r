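{
  "name": "igf1r_3pt",
  "comment": "Three-feature ligand-based pharmacophore for IGF-1R inhibitors: aromatic-hydrophobic, hydrophobic and hydrogen-bond-acceptor feature spheres with pairwise distance constraints in Angstrom.",
  "features": [
    {"label": "F1", "type": "HYD_ARO", "radius": 1.4},
    {"label": "F2", "type": "HYD", "radius": 0.8},
    {"label": "F3", "type": "HBA", "radius": 0.9}
  ],
  "distances": [
    [0.0, 3.75, 4.99],
    [3.75, 0.0, 6.79],
    [4.99, 6.79, 0.0]
  ]
}
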