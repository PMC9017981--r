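# Default model parameters (flat key-value; any subset may be overridden).
sa_normoxia_pct: 98.0
sv_normoxia_pct: 30.0
sv_min_pct: 10.0
samh_intercept_pct: 107.6
samh_slope_pct_per_m: -0.0066
p50_mmHg: 29.11
hill_exponent: 0.3704
venous_pH: 7.32
q_ratio: 1.0
a_ratio: 1.0
hb_ratio_ref: 1.2
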