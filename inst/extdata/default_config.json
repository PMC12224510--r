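{
  "simulation": {
    "n_per_group": { "control": 12, "copd_gold12": 12 },
    "shape": [24, 24, 24],
    "n_phases": 7,
    "master_seed": 1
  },
  "search": {
    "positive_group": "copd_gold12",
    "negative_group": "control",
    "max_dim": 4,
    "k": 3,
    "repeats": 100,
    "seed": 1,
    "budget": 20000,
    "beam": 25,
    "lambda": 1e-4
  },
  "report": {
    "top_n": 20,
    "render_figures": true
  }
}
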