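{
  "presynaptic": {"born_first": 0.375, "born_second": 0.125},
  "postsynaptic": {"born_first": 0.125, "born_second": 0.375}
}
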