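fusion_id	variant_label	mode	junction_probes	partner5	partner3	fwd_primer	rev_primer
AML1-ETO		standard	AML1-ETO	AML1ex5	ETO	AML1_F	ETO_R
PML-RARA	L-form	standard	PML-RARA-L	PML-L	RARA	PML-L_F	RARA_R
PML-RARA	S-form	standard	PML-RARA-S	PML-S	RARA	PML-S_F	RARA_R
PLZF-RARA		standard	PLZF-RARA	PLZF	RARA	PLZF_F	RARA_R
NPM1-RARA	L-form	standard	NPM1-RARA-L-1;NPM1-RARA-L-2	NPM1	RARA	NPM1_F	RARA_R
NPM1-RARA	S-form	standard	NPM1-RARA-S	NPM1	RARA	NPM1_F	RARA_R
CBFB-MYH11	A	standard	CBFB-MYH11-A	CBFB	MYH11-A	CBFB_F	MYH11-A_R
CBFB-MYH11	D	standard	CBFB-MYH11-D	CBFB	MYH11-DE	CBFB_F	MYH11-DE_R
CBFB-MYH11	E	standard	CBFB-MYH11-E	CBFB	MYH11-DE	CBFB_F	MYH11-DE_R
TEL-AML1	TEL-AML1ex2	standard	TEL-AML1ex2	TEL	AML1ex3	TEL_F	AML1_R
TEL-AML1	TEL-AML1ex3	standard	TEL-AML1ex3	TEL	AML1ex3	TEL_F	AML1_R
E2A-PBX1	I	standard	E2A-PBX1-I	E2A	PBX1	E2A_F	PBX1_R
E2A-PBX1	Ia	standard	E2A-PBX1-Ia	E2A	PBX1	E2A_F	PBX1_R
BCR-ABL	p190	standard	p190	BCR190	ABL	BCR-190_F	ABL_R
BCR-ABL	p210-b2a2	standard	p210-b2a2	BCR210	ABL	BCR-210_F	ABL_R
BCR-ABL	p210-b3a2	standard	p210-b3a2	BCR210	ABL	BCR-210_F	ABL_R
BCR-ABL	p230	standard	p230	BCR230	ABL	BCR-230_F	ABL_R
SIL-TAL1	I	standard	SIL-TAL1-I	SIL	TAL1	SIL_F	TAL1_R
SIL-TAL1	II	standard	SIL-TAL1-II	SIL	TAL1	SIL_F	TAL1_R
SIL-TAL1	III	standard	SIL-TAL1-III	SIL	TAL1	SIL_F	TAL1_R
MLL-AF4		mll		MLL	AF4	MLL_F	AF4_R
MLL-AF9		mll		MLL	AF9	MLL_F	AF9_R
MLL-ENL		mll		MLL	ENL	MLL_F	ENL_R
MLL-ELL		mll		MLL	ELL	MLL_F	ELL_R
MLL-AF6		mll		MLL	AF6	MLL_F	AF6_R
MLL-AF10	A	mll		MLL	AF10-A	MLL_F	AF10-A_R
MLL-AF10	B	mll		MLL	AF10-B	MLL_F	AF10-B_R
GUS		control		GUS		GUS_F	GUS_R
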