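{
  "model": "chemostat",
  "params": {
    "phi": 2, "mu1": 1600, "mu2": 1600,
    "s0_in": 50, "s1_in": 1, "s2_in": 1,
    "k10": 200, "k12": 200, "k20": 200, "k21": 200,
    "nu01": -1, "nu02": -1, "nu11": 0.2, "nu12": -0.1,
    "nu21": -0.1, "nu22": 0.2
  },
  "operation": { "name": "fixedpoints" },
  "seed": 0
}
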