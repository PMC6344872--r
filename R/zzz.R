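utils::globalVariables(c(
  ".", ".N", ".BY", ".SD", "prob", "log_weight", "acceptor_class",
  "acceptor_pos", "n_reads", "sa1", "kmer", "id", "delta_g", "off"
))
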