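{
  "name": "CARM1-style-4feat",
  "features": [
    {"kind": "donor", "center": [0.0, 0.0, 0.0], "radius": 1.0},
    {"kind": "aromatic", "center": [4.5, 0.0, 0.0], "radius": 1.0},
    {"kind": "aromatic", "center": [2.2, 4.2, 0.0], "radius": 1.0},
    {"kind": "hydrophobic", "center": [2.3, 1.6, 3.9], "radius": 1.0}
  ]
}
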