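probe_id	sequence	role	fusion_ids	variant_label	array_position
AML1-ETO	CCCGAGAACCTCGAAATCGTACTGAGAAG	junction	AML1-ETO		A-1abc
AML1ex5	CTCAGGTTTGTCGGTCGAAGTGGAAGAGG	partner	AML1-ETO		A-2abc
ETO	GCCAGACTCACCTGTGGATGTGAAGACGCAA	partner	AML1-ETO		A-3abc
PML-RARA-L	CCGGGGAGGCAGCCATTGAGACCCAGAG	junction	PML-RARA	L-form	B-1abc
PML-RARA-S	CACCCAGGGGAAAGCCATTGAGACCCAGAG	junction	PML-RARA	S-form	B-2abc
PML-L	CAGAAGAGGAAGTGCAGCCAGACCCAGTGCC	partner	PML-RARA		B-3abc
PML-S	AGAGGATGAAGTGCTACGCCTCGGACCAG	partner	PML-RARA		B-4abc
RARA	CCCTCTACCCCGCATCTACAAGCCTTGCTT	partner	PML-RARA;PLZF-RARA;NPM1-RARA		B-5abc
PLZF-RARA	CTTACTGGCTCATTCAGCCATTGAGACCCAGA	junction	PLZF-RARA		C-1abc
PLZF	GGGATGAAGACGTACGGGTGCGAGCTCTG	partner	PLZF-RARA		C-2abc
NPM1-RARA-L-1	AGGAGGAGGATGTGAACAGGGTTTTATTTATGAA	junction	NPM1-RARA	L-form	C-3abc
NPM1-RARA-L-2	GTTGGAAATTGGCAGCCATTGAGACCCAGA	junction	NPM1-RARA	L-form	C-4abc
NPM1-RARA-S	GTGGACAGCACTTAGTAGCCATTGAGACCCAGA	junction	NPM1-RARA	S-form	C-5abc
NPM1	ACACCACCAGTGGTCTTAAGGTTGAAGTGTGG	partner	NPM1-RARA		C-6abc
CBFB-MYH11-A	CGGGAGGAAATGGAGGTCCATGAGCTGGAGA	junction	CBFB-MYH11	A	D-1abc
CBFB-MYH11-D	CGGGAGGAAATGGAGAATGAAGTTGAGAGCG	junction	CBFB-MYH11	D	D-2abc
CBFB-MYH11-E	CGGGAGGAAATGGAGGCCAAGGCGAACC	junction	CBFB-MYH11	E	D-3abc
CBFB	CACGCGAATTTGAAGATAGAGACAGGTCTCA	partner	CBFB-MYH11		D-4abc
MYH11-A	ACCCAGATGGAGGAGATGAAGACGCAGC	partner	CBFB-MYH11		D-5abc
MYH11-DE	GACACCCAGGAGTTGCTTCAAGAA	partner	CBFB-MYH11		D-6abc
AF9	ACCTGGAAACATCTGGAACATCCTGAGGA	partner	MLL-AF9		E-1abc
ENL	GGGTTCACTCACGACTGGATGGTGTTTGTCCG	partner	MLL-ENL		E-2abc
ELL	CCAGCAGTATGTCTCCAGTCATGGGGAAGT	partner	MLL-ELL		E-3abc
AF6	TTCGACCTGATATGCGAATGCTGTCCTCTC	partner	MLL-AF6		E-4abc
AF10-A	GCTTACAGATTCGCTATGATCAACCAGGCA	partner	MLL-AF10	A	E-5abc
AF10-B	GTTTCAGAGACTAGAGGGTCAGAGGGCA	partner	MLL-AF10	B	E-6abc
MLL	CCCAAAACCACTCCTAGTGAGCCCA	partner	MLL-AF4;MLL-AF9;MLL-ENL;MLL-ELL;MLL-AF6;MLL-AF10		F-1abc
AF4	TCAAAAACTCACTCAAATTCTCAGCAAG	partner	MLL-AF4		F-2abc
TEL-AML1ex2	ATTGGGAGAATAGCAGAATGCATACTTGGAATG	junction	TEL-AML1	TEL-AML1ex2	G-1abc
TEL-AML1ex3	ATTGGGAGAATAGCAGATGCCAGCACGAGC	junction	TEL-AML1	TEL-AML1ex3	G-2abc
TEL	ATCGGGAAGACCTGGCTTACATGA	partner	TEL-AML1		G-3abc
AML1ex3	GCCGCTTCACGCCGCCTTCCACCGC	partner	TEL-AML1		G-4abc
E2A-PBX1-I	CCCGACTCCTACAGTGTTTTGAGTATCCGAGG	junction	E2A-PBX1	I	H-1abc
E2A-PBX1-Ia	TACAGTGATGAAAGTGTTCGGTCACCTGGAACCTTTTTG	junction	E2A-PBX1	Ia	H-2abc
E2A	CCTCAGGTTTCACCGGCCCCATGTCACT	partner	E2A-PBX1		H-3abc
PBX1	TGGACAACATGCTGTTAGCGGAAGGCGTGG	partner	E2A-PBX1		H-4abc
SIL-TAL1-I	CGCGGAAGTTGCGGATGACCGAGCGGC	junction	SIL-TAL1	I	I-1abc
SIL-TAL1-II	CGCGGAAGTTGCGATCGCCCAGGACCA	junction	SIL-TAL1	II	I-2abc
SIL-TAL1-III	CCTCCCAAAATGCTGATCGCCCAGGACCA	junction	SIL-TAL1	III	I-3abc
SIL	GGCTCCCGCTCCTACCCTGCAAACAGA	partner	SIL-TAL1		I-4abc
TAL1	GCCGAGCGAGGCGGCTCGCAGTGACCC	partner	SIL-TAL1		I-5abc
p190	TTCCATGGAGACGCAGAAGCCCTTCAGCGGC	junction	BCR-ABL	p190	J-1abc
BCR190	GGGCGTCCGCAAGACCGGGCAGATCTGG	partner	BCR-ABL		J-2abc
p210-b2a2	TGACCATCAATAAGGAAGAAGCCCTTCAGCG	junction	BCR-ABL	p210-b2a2	K-1abc
p210-b3a2	CTGGATTTAAGCAGAGTTCAAAAGCCCTTCAGCGGC	junction	BCR-ABL	p210-b3a2	K-2abc
BCR210	AGAACATCCGGGAGCAGCAGAAGAAGTGTTT	partner	BCR-ABL		K-3abc
p230	AGCCTTCGACGTCAAAGCCCTTCAGCG	junction	BCR-ABL	p230	K-4abc
BCR230	TGGAGGAGATCGAGCGCCGAGGCATGGAGG	partner	BCR-ABL		K-5abc
ABL	CCAAGGCTGGGTCCCAAGCAACTACATCACG	partner	BCR-ABL		K-6abc
GUS	CAGTCACCGACGAGAGTGCTGGGGA	control	GUS		L-1abc;L-3abc;L-5abc
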