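version: 1
design: pooled
scenario: alternative
theta: 0.92
theta_star: 0.1
n_arm: 50
look_interval: 10
prior: [0.5, 0.5]
n_sim: 1000
seed: 1
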