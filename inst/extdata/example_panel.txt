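ABL2
BORCS8
DAPK1
FBXO7
GLA
GLB1
LRRK2
VPS33B
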