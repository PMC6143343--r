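# Demo run configuration: a small autogamy experiment that completes in
# well under a minute on one CPU.
seed: 1
sim:
  n_scaffolds: 2
  scaffold_len: 8000
  n_ies: 40
  coverage: 60
  retention_prob: 0.5
  error_rate: 0.05
control:
  retention_prob: 0.01
  error_rate: 0.02
alpha: 0.05
bin_width: 0.025
min_shift: 3
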