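symbol	degree
CXCR4	17
CXCL9	16
CCR5	18
CXCR3	16
CCR2	14
CXCL10	19
CCL5	18
CXCL6	14
CXCL13	14
ADCY2	14
CCL25	14
PNOC	13
NPY1R	13
CXCL11	13
KIF11	17
KIF20A	17
CDC20	17
TYMS	15
RRM2	14
MAD2L1	15
DTL	13
ASPM	13
NDC80	13
MELK	13
RAD51AP1	12
CEP55	12
DLGAP5	12
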