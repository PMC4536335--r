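# Example simulation scenario: two single agents plus a synergistic
# 50:50 constant-ratio mixture, a 47-gene planted signature among null
# genes, and survival with a score-dependent hazard.
seed: 1
drug_a: {Dm: 1.0, m: 1.2}
drug_b: {Dm: 4.0, m: 1.2}
fraction_a: 0.5
m_combo: 1.2
target_ci: 0.5
noise_cv: 0.05
n_samples: 30
n_signal_genes: 47
n_null_genes: 103
target_r: 0.95
hazard_ratio: 2.5
censoring_rate: 0.3
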