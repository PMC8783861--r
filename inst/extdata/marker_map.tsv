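population	gene
B cells	BLK
B cells	CD19
B cells	MS4A1
B cells	TNFRSF17
B cells	FCRL2
B cells	FAM30A
B cells	PNOC
B cells	SPIB
B cells	TCL1A
CD45+ cells	PTPRC
CD56dim NK cells	KIR2DL3
CD56dim NK cells	KIR3DL1
CD56dim NK cells	KIR3DL2
CD56dim NK cells	IL21R
CD8+ T cells	CD8A
CD8+ T cells	CD8B
Cytotoxic cells	PRF1
Cytotoxic cells	GZMA
Cytotoxic cells	GZMB
Cytotoxic cells	GZMH
Cytotoxic cells	GNLY
Cytotoxic cells	CTSW
Cytotoxic cells	KLRB1
Cytotoxic cells	KLRD1
Cytotoxic cells	KLRK1
Cytotoxic cells	NKG7
Dendritic cells	CCL13
Dendritic cells	CD209
Dendritic cells	HSD11B1
Exhausted CD8+ T cells	CD244
Exhausted CD8+ T cells	EOMES
Exhausted CD8+ T cells	LAG3
Exhausted CD8+ T cells	PTGER4
Macrophages	CD163
Macrophages	CD68
Macrophages	CD84
Macrophages	MS4A4A
Mast cells	MS4A2
Mast cells	TPSAB1
Mast cells	CPA3
Mast cells	HDC
Neutrophils	CEACAM3
Neutrophils	CSF3R
Neutrophils	FCAR
Neutrophils	FCGR3B
Neutrophils	FPR1
Neutrophils	S100A12
Neutrophils	SIGLEC5
NK cells	NCR1
NK cells	XCL1
NK cells	XCL2
T cells	CD3D
T cells	CD3E
T cells	CD3G
T cells	CD6
T cells	SH2D1A
T cells	TRAT1
Th1 cells	TBX21
Treg cells	FOXP3
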