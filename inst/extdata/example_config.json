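{
  "growth": {"l_inf": 180, "k": 0.1, "t0": 0,
             "radius_slope": 12.5, "radius_intercept": 0},
  "lod_min_fraction": 0.95,
  "cohort_min_year": 1989,
  "cohort_max_year": 2002,
  "bcp_p0": 0.2,
  "bcp_w0": 0.2,
  "bcp_n_iter": 10000,
  "bcp_burn_in": 5000,
  "mc_iterations": 5000,
  "bias_radius_km": 100,
  "bias_layer_m": 100,
  "strata_bounds": [0, 50, 100, 200, 300, 400, 500],
  "seed": 1
}
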