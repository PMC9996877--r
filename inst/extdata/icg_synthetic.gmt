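immune_checkpoint	immune checkpoint genes, curated synthetic reconstruction	PDCD1	CD274	PDCD1LG2	CTLA4	CD276	ADORA2A	BTLA	BTNL2	CD160	CD200	CD200R1	CD244	CD27	CD28	CD40	CD40LG	CD44	CD48	CD70	CD80	CD86	HAVCR2	HHLA2	ICOS	ICOSLG	IDO1	IDO2	KIR3DL1	LAG3	LAIR1	LGALS9	NRP1	TIGIT	TMIGD2	TNFRSF14	TNFRSF18	TNFRSF25	TNFRSF4	TNFRSF8	TNFRSF9	TNFSF14	TNFSF15	TNFSF18	TNFSF4	TNFSF9	VSIR	VTCN1	CD226	CD96	PVR	NECTIN2	CEACAM1	KIR2DL1	KIR2DL3	TDO2	SIGLEC15	CD47	SIRPA	BTN3A1	BTN3A2
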