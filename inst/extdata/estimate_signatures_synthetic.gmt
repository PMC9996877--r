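stromal_signature	synthetic placeholder stromal signature	COL1A1	COL1A2	COL3A1	COL5A1	COL6A3	FAP	FN1	ACTA2	PDGFRA	PDGFRB	THY1	DCN	LUM	POSTN	SPARC	VIM	ZEB1	TAGLN	MMP2	FBLN1
immune_signature	synthetic placeholder immune signature	PTPRC	CD2	CD3D	CD3E	CD8A	CD19	MS4A1	CD79A	GZMB	PRF1	IL7R	CCL5	CXCL9	CXCL10	LCK	ZAP70	HLA-DRA	HLA-DRB1	FCGR3A	NKG7
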