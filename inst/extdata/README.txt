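synthetic_gcal_points.tsv
  SYNTHETIC example dose-response table (not digitized experimental data):
  points generated from the default g_CaL concentration-response relation
  (max 0.54, K0.5 7 nM) with additive Gaussian noise (sd 0.02, seed 7).
  Columns: dose (nM), response (fractional increase).
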