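{
  "model": "dv",
  "phantom": "prostate",
  "prescription": "prostate",
  "beams": {
    "gantry_angles_deg": [36, 100, 180, 260, 324],
    "beamlet_width": 5,
    "field_margin_mm": 10
  },
  "kernel": {
    "mu_attenuation": 0.005,
    "sigma_penumbra": 3,
    "floor_frac": 1e-4
  },
  "solver": {
    "max_iters": 50,
    "tol": 1e-6,
    "history_size": 10
  },
  "loop": {
    "inner_adjust_iters": 5,
    "max_compensation_iters": 10
  },
  "seed": 1,
  "push_coverage": false,
  "out_dir": "."
}
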