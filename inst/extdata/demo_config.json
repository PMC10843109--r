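{
  "out_dir": "demo_out",
  "seed": 3,
  "threshold_kn": 34,
  "exclusion_days": 60,
  "knots_per_year": 6,
  "meta_df": 2,
  "causes": ["all"],
  "rain_window": 2,
  "simulate": {
    "n_storms": 5,
    "n_locations": 12,
    "years": 15,
    "region": [120, 135, 10, 30],
    "effect": { "shape": "rect", "peak": 0.3, "duration": 21 }
  }
}
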