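ligand	receptor	pair_id
TNF	TNFRSF1A	TNF_TNFRSF1A
TNF	TNFRSF1B	TNF_TNFRSF1B
IL1B	IL1R1	IL1B_IL1R1
IL6	IL6R	IL6_IL6R
IL10	IL10RA	IL10_IL10RA
CXCL8	CXCR1	CXCL8_CXCR1
CXCL8	CXCR2	CXCL8_CXCR2
CXCL12	CXCR4	CXCL12_CXCR4
CCL2	CCR2	CCL2_CCR2
CSF1	CSF1R	CSF1_CSF1R
TGFB1	TGFBR1	TGFB1_TGFBR1
TGFB1	TGFBR2	TGFB1_TGFBR2
VEGFA	KDR	VEGFA_KDR
PDGFB	PDGFRB	PDGFB_PDGFRB
ICAM1	ITGB2	ICAM1_ITGB2
FN1	ITGA5	FN1_ITGA5
FN1	ITGB1	FN1_ITGB1
APOE	LRP1	APOE_LRP1
GAS6	MERTK	GAS6_MERTK
ANXA1	FPR2	ANXA1_FPR2
MIF	CD74	MIF_CD74
SPP1	CD44	SPP1_CD44
LGALS9	HAVCR2	LGALS9_HAVCR2
NAMPT	INSR	NAMPT_INSR
UNMAPPEDLIG	IL1R1	UNMAPPEDLIG_IL1R1
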