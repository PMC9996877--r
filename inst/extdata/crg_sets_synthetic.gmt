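clock_control	clock-control (output/stabilizing loop) genes, curated synthetic reconstruction	RORA	RORB	RORC	NR1D1	NR1D2	DBP	TEF	HLF	NFIL3	KLF10	FBXL3	SERPINE1	CIART
core_clock	core-clock (primary feedback loop) genes, curated synthetic reconstruction	CLOCK	ARNTL	ARNTL2	NPAS2	PER1	PER2	PER3	CRY1	CRY2	CSNK1A1	CSNK1D	CSNK1E	CSNK2A1	CSNK2B	TIMELESS	TIPIN	METTL3	BHLHE40	BHLHE41	HCRTR2	MTNR1A	MTNR1B	NPFF	AUTS2	REV1	GSK3B	FBXW11	BTRC	PRKAA1	PRKAA2	NONO	SFPQ	CUL1	FBXL21	SIRT1
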