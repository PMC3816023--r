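name	direction	tag	tag_seq	gene_specific_seq	accession	start_1based	stated_len	biotin
ETO_R	reverse	SP6	ATTTAGGTGACACTATAGA	GAACTCTTTCTCCTATCT	D14289	614	18	0
RARA_R	reverse	SP6	ATTTAGGTGACACTATAGA	CGGTCGTTTCTCACAG	X06538	696	16	0
MYH11-A_R	reverse	SP6	ATTTAGGTGACACTATAGA	TTGCGTAGCTGCTTGATG	D10667	2271	18	0
MYH11-DE_R	reverse	SP6	ATTTAGGTGACACTATAGA	GCAGGCTGTTCCGCT	D10667	1374	15	0
AML1_R	reverse	SP6	ATTTAGGTGACACTATAGA	CACGGAGCAGAGGAAGT	D43969	731	17	0
PBX1_R	reverse	SP6	ATTTAGGTGACACTATAGA	TCGCAGGAGATTCATCACG	M86546	657	19	0
TAL1_R	reverse	SP6	ATTTAGGTGACACTATAGA	CGTCCCTCTAGCTGG	S53245	257	15	0
ABL_R	reverse	SP6	ATTTAGGTGACACTATAGA	AGCTGCCATTGATCCCG	X16416	576	17	0
AF9_R	reverse	SP6	ATTTAGGTGACACTATAGA	TTCTTGATGCATCCAGTTGT	L13744	1910	20	0
ENL_R	reverse	SP6	ATTTAGGTGACACTATAGA	GACCACCTTCTCCACGAAGT	D14539	301	20	0
ELL_R	reverse	SP6	ATTTAGGTGACACTATAGA	GTAGCGGCCTCCAGCCT	U16282	461	17	0
AF6_R	reverse	SP6	ATTTAGGTGACACTATAGA	AATCTGCCTTCCCGATCA	U02478	360	18	0
AF10-A_R	reverse	SP6	ATTTAGGTGACACTATAGA	CACTGCCTCTCCAAAAGCT	U13948	2384	19	0
AF10-B_R	reverse	SP6	ATTTAGGTGACACTATAGA	TGACCTGAGCTGTGAGCT	U13948	1146	18	0
AF4_R	reverse	SP6	ATTTAGGTGACACTATAGA	TCGAGCATGGATGACGTT	L13773	1674	18	0
GUS_R	reverse	SP6	ATTTAGGTGACACTATAGA	TGCCGTGAACAGTCCAGG	M15182	2057	18	0
AML1_F	forward	T7	TAATACGACTCACTATAGGGA	CCAGGTTGCAAGATTTAATGAC	D43969	903	22	0
PML-L_F	forward	T7	TAATACGACTCACTATAGGGA	CAGTGTACGCCTTCTCCATCA	M73778	1438	19	0
PML-S_F	forward	T7	TAATACGACTCACTATAGGGA	GTGCGCCAGGTGGTAGCTC	M73778	927	25	0
PLZF_F	forward	T7	TAATACGACTCACTATAGGGA	CCACAAGGCTGACGCTGTATT	Z19002	1092	21	0
NPM1_F	forward	T7	TAATACGACTCACTATAGGGA	ACGAAGGCAGTCCAATTAAAGTAAC	X16934	160	25	0
CBFB_F	forward	T7	TAATACGACTCACTATAGGGA	TTTGAAGGCTCCCATGATTCTG	L20298	267	22	0
TEL_F	forward	T7	TAATACGACTCACTATAGGGA	CACTCCGTGGATTTCAAACAGTC	U11732	871	23	0
E2A_F	forward	T7	TAATACGACTCACTATAGGGA	AAGATAGAAGACCACCTGGACG	M31222	1243	22	0
SIL_F	forward	T7	TAATACGACTCACTATAGGGA	CGACCCCAACGTCCCAGAG	M74558	24	19	0
BCR-190_F	forward	T7	TAATACGACTCACTATAGGGA	CGCTCTCCCTCGCAGAACT	X02596	1590	20	0
BCR-210_F	forward	T7	TAATACGACTCACTATAGGGA	GAGTCACTGCTGCTGCTTATGTC	X02596	2952	24	0
BCR-230_F	forward	T7	TAATACGACTCACTATAGGGA	CCAAGGTGCCCTACATCGT	X02596	3682	19	0
MLL_F	forward	T7	TAATACGACTCACTATAGGGA	CCGCCTCAGCCACCTACTAC	L04284	3916	20	0
GUS_F	forward	T7	TAATACGACTCACTATAGGGA	GGAATTTTGCCGATTTCATG	M15182	1786	20	0
T7	forward	T7	TAATACGACTCACTATAGGGA		NA	NA	21	0
SP6	reverse	SP6	ATTTAGGTGACACTATAGA		NA	NA	19	0
SP6-biotin	reverse	SP6	ATTTAGGTGACACTATAGA		NA	NA	19	1
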