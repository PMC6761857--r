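# silence R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  "window_id", "site_idx", "n_maj", "n_min", "n_snps", "sum_nmaj",
  "sum_nmin", "hp", "zhp", "fst", "a", "abc", "sum_a", "sum_abc",
  "loglik", "het", "f", "start", "end"))
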