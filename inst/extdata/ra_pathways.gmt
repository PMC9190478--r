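hsa04659	Th17 cell differentiation	HLA-DMB	HLA-DOB	CD247	CD3D	LCK	IL1R1	JUN	IL21R	IL2RG	HLA-DPB1
hsa05323	Rheumatoid arthritis	HLA-DMB	HLA-DOB	CCL5	IL15	JUN	HLA-DPB1	ITGB2	CXCL6	TNFSF11
hsa04064	NF-kappa B signaling pathway	GADD45B	BLNK	LCK	PRKCB	IL1R1	PLCG2	BIRC3	TNFSF11	BCL2A1
hsa04668	TNF signaling pathway	CCL5	JUNB	SOCS3	IL15	JUN	BIRC3	CXCL10	CXCL6	MMP9
hsa04658	Th1 and Th2 cell differentiation	HLA-DMB	HLA-DOB	CD247	CD3D	LCK	JUN	IL2RG	HLA-DPB1
hsa04620	Toll-like receptor signaling pathway	CCL5	TLR7	JUN	CXCL9	CXCL11	TLR8	CXCL10	SPP1
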