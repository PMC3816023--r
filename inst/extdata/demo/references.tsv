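sample_id	group	diagnosis	method
AML_001	AML	AML1-ETO	FISH
AML_002	AML	PML-RARA:S-form	RT-PCR
AML_003	AML	none	cytogenetics
AML_004	AML	none	FISH
ALL_001	ALL	TEL-AML1:TEL-AML1ex2	FISH
ALL_002	ALL	other_translocation	RT-PCR
ALL_003	ALL	none	cytogenetics
CML_001	CML	BCR-ABL:p210-b3a2	FISH
CML_002	CML	none	RT-PCR
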