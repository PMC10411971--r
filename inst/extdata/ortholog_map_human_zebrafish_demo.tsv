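human_gene	target_gene
TNF	tnfa
TNF	tnfb
TNFRSF1A	tnfrsf1a
TNFRSF1B	tnfrsf1b
IL1B	il1b
IL1R1	il1r1
IL6	il6
IL6R	il6r
IL10	il10
IL10RA	il10ra
CXCL8	cxcl8a
CXCL8	cxcl8b.1
CXCR1	cxcr1
CXCR2	cxcr2
CXCL12	cxcl12a
CXCL12	cxcl12b
CXCR4	cxcr4a
CXCR4	cxcr4b
CCL2	ccl2
CCR2	ccr2
CSF1	csf1a
CSF1	csf1b
CSF1R	csf1ra
CSF1R	csf1rb
TGFB1	tgfb1a
TGFB1	tgfb1b
TGFBR1	tgfbr1a
TGFBR1	tgfbr1b
TGFBR2	tgfbr2a
TGFBR2	tgfbr2b
VEGFA	vegfaa
VEGFA	vegfab
KDR	kdr
KDR	kdrl
PDGFB	pdgfba
PDGFB	pdgfbb
PDGFRB	pdgfrb
ICAM1	icam1
ITGB2	itgb2
FN1	fn1a
FN1	fn1b
ITGA5	itga5
ITGB1	itgb1a
ITGB1	itgb1b.1
APOE	apoea
APOE	apoeb
LRP1	lrp1aa
LRP1	lrp1ab
GAS6	gas6
MERTK	mertka
ANXA1	anxa1a
ANXA1	anxa1b
FPR2	fpr1
MIF	mif
CD74	cd74a
CD74	cd74b
SPP1	spp1
CD44	cd44a
CD44	cd44b
LGALS9	lgals9l1
HAVCR2	havcr2
NAMPT	nampta
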