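pi3k_akt	reconstructed: PI3K/AKT/mTOR signalling members assembled from public pathway annotation, NOT the exact 88-gene MSigDB selection used upstream; replace via the gmt argument for exact reproduction	AKT1	AKT2	AKT3	PIK3CA	PIK3CB	PIK3R1	PIK3R2	PDPK1	MTOR	RPTOR	RICTOR	RHEB	TSC1	TSC2	PTEN	GSK3A	GSK3B	FOXO1	FOXO3	EIF4E	EIF4EBP1	RPS6KB1	RPS6	AKT1S1	DEPTOR	MLST8	INPP5D	PPP2CA	BAD	MDM2	TBC1D4	SREBF1	HIF1A	VEGFA	IRS1	IGF1R	INSR	PIK3R3	PHLPP1	CDKN1B
proliferation_markers	reconstructed: partial list of canonical proliferation markers (MKI67, MCM complex, PLK1, PCNA and cell-cycle effectors), standing in for the cited 157-marker catalogue; replace via the gmt argument for exact reproduction	MKI67	PCNA	PLK1	MCM2	MCM3	MCM4	MCM5	MCM6	MCM7	TOP2A	CCNB1	CCNA2	CCNE1	CDK1	CDK2	CDK4	CDK6	CDC20	CDC6	CDC45	AURKA	AURKB	BUB1	BUB1B	BIRC5	FOXM1	E2F1	TYMS	RRM1	RRM2	GINS1	GINS2	CDT1	ORC1	ORC6	KIF11	KIF23	CENPA	CENPE	CENPF	TPX2	PBK	TK1	EXO1	FEN1	POLA1	POLE	RFC4	CHEK1	TTK
undifferentiated	reconstructed: invasive/undifferentiated melanoma state markers (AXL-high program) assembled from the melanoma dedifferentiation literature; synthetic stand-in for the cited subtype signature	AXL	EGFR	ZEB1	SMAD3	TGFBI	FOSL1	ITGA3	SERPINE1	CDH2	VIM	THBS1	TNC
neural_crest_like	reconstructed: neural-crest-like drug-tolerant state markers (NGFR-high program); synthetic stand-in for the cited subtype signature	NGFR	GFRA2	GFRA3	PLXNC1	L1CAM	NES	TFAP2B	POSTN	S100B	CDH19
transitory	reconstructed: transitory intermediate-state markers along the melanoma differentiation trajectory; synthetic stand-in for the cited subtype signature	SOX10	TFAP2A	PAX3	KIT	ERBB3	MLPH	RAB27A	GPR143
melanocytic	reconstructed: melanocytic/differentiated pigmentation program markers; synthetic stand-in for the cited subtype signature	MITF	TYR	TYRP1	DCT	PMEL	MLANA	SLC45A2	OCA2	EDNRB	BCL2
cc_g1	reconstructed: minimal G1-phase marker set in the style of the cyclebase catalogue; user-suppliable via the gmt argument	CCNE1	CCNE2	CDC6	CDT1	SLBP	MCM2	MCM6
cc_s	reconstructed: minimal S-phase marker set in the style of the cyclebase catalogue; user-suppliable via the gmt argument	PCNA	RRM2	TYMS	FEN1	CDC45	GINS2	CLSPN
cc_g2	reconstructed: minimal G2-phase marker set in the style of the cyclebase catalogue; user-suppliable via the gmt argument	CCNA2	TOP2A	CDK1	FOXM1	CENPF	NDC80
cc_m	reconstructed: minimal M-phase marker set in the style of the cyclebase catalogue; user-suppliable via the gmt argument	CCNB1	CCNB2	PLK1	BUB1	CDC20	AURKB	UBE2C	KIF2C
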