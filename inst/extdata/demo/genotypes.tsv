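sample_id	group	fusion_id	variant_label	include_control
AML_001	AML	AML1-ETO		1
AML_002	AML	PML-RARA	S-form	1
AML_003	AML			0
AML_004	AML			1
ALL_001	ALL	TEL-AML1	TEL-AML1ex2	1
ALL_002	ALL			1
ALL_003	ALL			1
CML_001	CML	BCR-ABL	p210-b3a2	1
CML_002	CML			1
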