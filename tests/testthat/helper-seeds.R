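# derive distinct but reproducible integer seeds for multi-sample tests
child_seed_for_test <- function(seed, tag) {
  h <- sum(utf8ToInt(tag))
  as.integer((seed * 131 + h) %% 2000000011)
}
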