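{
  "model": "elv",
  "params": {
    "d": 2, "r1": 0.027, "r2": 0.027,
    "a1": 50, "a2": 50,
    "b11": 5, "b12": 10, "b21": 10, "b22": 5,
    "c1": 0.2, "c2": 0.2
  },
  "operation": { "name": "fixedpoints" },
  "seed": 0
}
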