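[
  {"observable": "po", "value": 0.22, "tolerance": 0.01, "weight": 1,
   "note": "stationary open probability of the phosphorylated wild-type channel at 3 mM ATP (single-channel recording)"},
  {"observable": "pdim", "value": 0.85, "tolerance": 0.01, "weight": 1,
   "note": "stationary occupancy of NBD-dimerized (high-FRET) conformations at 3 mM ATP (smFRET)"},
  {"observable": "dwell_ratio", "value": 20, "tolerance": 0.05, "weight": 1,
   "note": "mean dwell of the NBD-dimerized class over mean open-burst dwell at saturating ATP (approximately 20-fold)"},
  {"observable": "tau_opening_s", "value": 0.49, "tolerance": 0.02, "weight": 1,
   "note": "mono-exponential activation constant of channel current after a saturating ATP jump (490 ms)"},
  {"observable": "tau_sep_fast_s", "value": 1.6, "tolerance": 0.03, "weight": 1,
   "note": "fast component of the bi-exponential decay of high-FRET occupancy after ATP withdrawal"},
  {"observable": "tau_sep_slow_s", "value": 20, "tolerance": 0.03, "weight": 1,
   "note": "slow component of the bi-exponential decay of high-FRET occupancy after ATP withdrawal"},
  {"observable": "ec50_open_M", "value": 53e-6, "tolerance": 0.015, "weight": 1,
   "note": "Hill midpoint (n = 1) of the ATP dose response of open probability (53 uM)"},
  {"observable": "ec50_dim_M", "value": 55e-6, "tolerance": 0.015, "weight": 1,
   "note": "Hill midpoint (n = 1) of the ATP dose response of high-FRET occupancy (55 uM)"},
  {"observable": "turnover_per_s", "window": [0.35, 0.95], "tolerance": 0.25, "weight": 1,
   "note": "ensemble ATP hydrolysis rate window (0.3-1 per second); kept soft because the cycle model is expected to sit at or above the measured range"}
]
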