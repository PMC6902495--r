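{
  "alpha": 0.025,
  "spending": {
    "lower_cumulative": [0.200, 0.600, 0.975],
    "upper_cumulative": [0.000, 0.001, 0.025]
  },
  "looks": {
    "counts": [[20, 15, 10], [25, 20, 15]]
  },
  "n_per_arm": 30,
  "model": {
    "sigmas": [18, 18, 18],
    "correlations": [[1.0, 0.0, 0.5], [0.0, 1.0, 0.5], [0.5, 0.5, 1.0]]
  },
  "lags": [3, 6, 12],
  "policy": {"binding": true, "looks_after_recruitment": true}
}
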