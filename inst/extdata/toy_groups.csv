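species,group
A1,g1
X1,g1
X2,g1
A2,g2
Y1,g2
Y2,g2
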