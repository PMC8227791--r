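CASP3
TP53
SOD2
GPX1
PPARA
PPARG
NES
GAP43
SUMO1
APOE
IGF1
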