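strategy,frequency_pct,transient_pct,developmental_pct,stable_pct
NP,41.5,38,36,43
XOR_FIRST,7.5,8,24,6
XOR_SECOND,18.9,8,24,8
XNOR,15.1,17,24,13
PN,45.3,86.2,91.1,85
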