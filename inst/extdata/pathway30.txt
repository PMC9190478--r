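BCL2A1
BIRC3
BLNK
CCL5
CD247
CD3D
CXCL10
CXCL11
CXCL6
CXCL9
GADD45B
HLA-DMB
HLA-DOB
HLA-DPB1
IL15
IL1R1
IL21R
IL2RG
ITGB2
JUN
JUNB
LCK
MMP9
PLCG2
PRKCB
SOCS3
SPP1
TLR7
TLR8
TNFSF11
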