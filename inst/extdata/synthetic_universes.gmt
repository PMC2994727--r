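STEMNESS_PANEL_SYNTHETIC	synthetic stand-in for a stemness-related gene panel	PROM1	ALDH1A1	KLF4	SOX2	POU5F1	NANOG	MYC	KIT	NES	NOTCH1	ABCG2	CD44	EPCAM	THY1	ITGA6	BMI1	LGR5	MSI1	DLL1	JAG1
ANGIOGENESIS_PANEL_SYNTHETIC	synthetic stand-in for an angiogenesis-related gene panel	VEGFA	VEGFB	VEGFC	KDR	FLT1	FLT4	ANGPT1	ANGPT2	TEK	PECAM1	CDH5	ENG	FGF2	FGFR1	PDGFB	PDGFRB	HIF1A	EPAS1	MMP2	MMP9
SIGNAL_TRANSDUCTION_PANEL_SYNTHETIC	synthetic stand-in for a cancer signal-transduction gene panel	PTGS2	EGFR	ERBB2	KRAS	HRAS	BRAF	MAP2K1	MAPK1	MAPK3	PIK3CA	AKT1	MTOR	PTEN	STAT3	JAK2	NFKB1	RELA	TP53	CCND1	CTNNB1	GSK3B	SMAD3	TGFB1	WNT1
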