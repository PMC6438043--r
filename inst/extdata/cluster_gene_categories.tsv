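cluster	category	gene
transient	developmental	ANXA1
transient	developmental	CAMK4
transient	developmental	CD8A
transient	developmental	CD27
transient	developmental	EOMES
transient	developmental	ITK
transient	developmental	JAK3
transient	developmental	LCK
transient	developmental	PTPN22
transient	developmental	PTPRC
transient	developmental	SASH3
transient	developmental	THEMIS
transient	immune	ANXA1
transient	immune	CAMK4
transient	immune	CCL5
transient	immune	CD8A
transient	immune	CD27
transient	immune	CD48
transient	immune	CD96
transient	immune	CD247
transient	immune	CORO1A
transient	immune	CST7
transient	immune	CXCL14
transient	immune	CXCL9
transient	immune	EOMES
transient	immune	FASLG
transient	immune	FYB
transient	immune	GZMA
transient	immune	HCST
transient	immune	IGLC1
transient	immune	IKZF1
transient	immune	IL16
transient	immune	IL7R
transient	immune	ITGAL
transient	immune	ITK
transient	immune	JAK3
transient	immune	KLHL6
transient	immune	LAT
transient	immune	LAX1
transient	immune	LCK
transient	immune	LCP2
transient	immune	LY9
transient	immune	PRKCB
transient	immune	PTPN22
transient	immune	PTPRC
transient	immune	SASH3
transient	immune	SELPLG
transient	immune	SEMA4D
transient	immune	SH2D1A
transient	immune	SLAMF1
transient	immune	THEMIS
transient	immune	TRAC
transient	immune	XCL1
long_term_changing	developmental	C3
long_term_changing	developmental	CCR2
long_term_changing	developmental	CD2
long_term_changing	developmental	CXCL10
long_term_changing	developmental	DACT1
long_term_changing	developmental	DKK3
long_term_changing	developmental	EAF2
long_term_changing	developmental	EPHA7
long_term_changing	developmental	FGF1
long_term_changing	developmental	FGFR2
long_term_changing	developmental	HCLS1
long_term_changing	developmental	HLA-DOA
long_term_changing	developmental	IL12RB1
long_term_changing	developmental	IRF4
long_term_changing	developmental	LAMA2
long_term_changing	developmental	OSR2
long_term_changing	developmental	PDGFRA
long_term_changing	developmental	SIPA1L1
long_term_changing	developmental	SPHK1
long_term_changing	immune	APOBEC3G
long_term_changing	immune	BLNK
long_term_changing	immune	C1S
long_term_changing	immune	C3
long_term_changing	immune	CCR2
long_term_changing	immune	CD2
long_term_changing	immune	CD3D
long_term_changing	immune	CD38
long_term_changing	immune	CRTAM
long_term_changing	immune	CXCL10
long_term_changing	immune	GPR183
long_term_changing	immune	HLA-DOA
long_term_changing	immune	HLA-DPB1
long_term_changing	immune	IGKC
long_term_changing	immune	IL12RB1
long_term_changing	immune	IRF4
long_term_changing	immune	LPXN
long_term_changing	immune	MZB1
long_term_changing	immune	NFATC2
long_term_changing	immune	PAWR
long_term_changing	immune	POU2AF1
long_term_changing	immune	PRKCQ
long_term_changing	immune	SAMSN1
long_term_changing	immune	SLAMF7
long_term_changing	immune	TRBC1
long_term_constant	developmental	BHLHE22
long_term_constant	developmental	CCL19
long_term_constant	developmental	CCL2
long_term_constant	developmental	DCN
long_term_constant	developmental	DSC3
long_term_constant	developmental	EGR3
long_term_constant	developmental	EPHB1
long_term_constant	developmental	FHL2
long_term_constant	developmental	FZD8
long_term_constant	developmental	GLI3
long_term_constant	developmental	GPR65
long_term_constant	developmental	KCNMA1
long_term_constant	developmental	KIF5C
long_term_constant	developmental	KRT5
long_term_constant	developmental	MYLK
long_term_constant	developmental	NFASC
long_term_constant	developmental	PRKCA
long_term_constant	developmental	SALL1
long_term_constant	developmental	SDC1
long_term_constant	developmental	SULF1
long_term_constant	developmental	SULF2
long_term_constant	developmental	TAGLN
long_term_constant	developmental	TREM2
long_term_constant	developmental	TYMS
long_term_constant	developmental	VCAM1
long_term_constant	developmental	WIPF3
long_term_constant	developmental	XDH
long_term_constant	developmental	ZIC1
long_term_constant	immune	CCL2
long_term_constant	immune	CCL19
long_term_constant	immune	GLI3
long_term_constant	immune	HLA-DPA1
long_term_constant	immune	HLA-DRA
long_term_constant	immune	VCAM1
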