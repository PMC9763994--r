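version: 1
design: enrichment
scenario: alternative
theta: 0.96
theta_star: 0.15
n_arm: 50
look_interval: 10
prior: [0.5, 0.5]
stage2_n: 100
stage1_bound_quantile: 0.8
n_sim: 1000
seed: 1
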