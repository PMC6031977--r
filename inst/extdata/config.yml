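# analysis configuration mirroring analysisConfig(); all keys optional
perm_reps: 9999
ccf_grid_days: 1
ccf_max_lag_days: 183
warn_threshold: 0.28
bloom_threshold: 1.0e+07
lead_days: 40
alpha: 0.05
seed: 1
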