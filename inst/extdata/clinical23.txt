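ABCG2
AKR1B1
ALOX5
CASP1
DHFR
DHODH
HRH4
IL2
JAK1
JAK2
JAK3
MMP9
NR3C1
PDE4A
PDE4B
PDE4D
PLA2G1B
PPARA
PTGS1
PTGS2
TLR7
TLR9
TNF
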