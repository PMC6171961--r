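POS	CM
1	0
50000	0.05
1e+05	0.1
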