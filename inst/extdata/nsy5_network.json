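{
  "classes": ["ADA", "ADF", "ADL", "AFD", "AIM", "AIZ", "ASH", "ASI", "ASK",
              "AWB", "AWC", "BAG", "RIC"],
  "pn_classes": ["ADA", "AIY", "AIZ", "ASK", "ADL", "AFD", "ASH", "AWC"]
}
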