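# prior hyperparameter sets examined in the sensitivity analysis
version: 1
priors:
  jeffreys: [0.5, 0.5]
  uniform: [1, 1]
  improper: [0, 0]
  weakly_informative: [2, 2]
  optimistic: [0.75, 0.25]
  pessimistic: [0.25, 0.75]
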