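{
  "n_genotyped_total": 1173,
  "n_curation_errors": 54
}
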