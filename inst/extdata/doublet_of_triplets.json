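{
  "name": "doublet_of_triplets",
  "j_names": ["J1", "J2"],
  "offsets": [
    [-0.5, -1], [-0.5, 0], [-0.5, 1],
    [ 0.5, -1], [ 0.5, 0], [ 0.5, 1]
  ],
  "weights": [1, 2, 1, 1, 2, 1],
  "specs": [
    {"name": "lw", "init": 0.002, "lower": 0.1, "upper": 10,
     "mode": "relative", "unit": "ppm"}
  ]
}
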