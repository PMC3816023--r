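row	col	replicate	content
TOP	0	1	BIOTIN
TOP	1	1	BIOTIN
TOP	2	1	BIOTIN
TOP	3	1	BIOTIN
TOP	4	1	BIOTIN
TOP	5	1	BIOTIN
TOP	6	1	BIOTIN
A	0	1	BIOTIN
A	1	1	AML1-ETO
A	1	2	AML1-ETO
A	1	3	AML1-ETO
A	2	1	AML1ex5
A	2	2	AML1ex5
A	2	3	AML1ex5
A	3	1	ETO
A	3	2	ETO
A	3	3	ETO
A	4	1	BLANK
A	4	2	BLANK
A	4	3	BLANK
A	5	1	BLANK
A	5	2	BLANK
A	5	3	BLANK
A	6	1	BLANK
A	6	2	BLANK
A	6	3	BLANK
B	0	1	BIOTIN
B	1	1	PML-RARA-L
B	1	2	PML-RARA-L
B	1	3	PML-RARA-L
B	2	1	PML-RARA-S
B	2	2	PML-RARA-S
B	2	3	PML-RARA-S
B	3	1	PML-L
B	3	2	PML-L
B	3	3	PML-L
B	4	1	PML-S
B	4	2	PML-S
B	4	3	PML-S
B	5	1	RARA
B	5	2	RARA
B	5	3	RARA
B	6	1	BLANK
B	6	2	BLANK
B	6	3	BLANK
C	0	1	BIOTIN
C	1	1	PLZF-RARA
C	1	2	PLZF-RARA
C	1	3	PLZF-RARA
C	2	1	PLZF
C	2	2	PLZF
C	2	3	PLZF
C	3	1	NPM1-RARA-L-1
C	3	2	NPM1-RARA-L-1
C	3	3	NPM1-RARA-L-1
C	4	1	NPM1-RARA-L-2
C	4	2	NPM1-RARA-L-2
C	4	3	NPM1-RARA-L-2
C	5	1	NPM1-RARA-S
C	5	2	NPM1-RARA-S
C	5	3	NPM1-RARA-S
C	6	1	NPM1
C	6	2	NPM1
C	6	3	NPM1
D	0	1	BIOTIN
D	1	1	CBFB-MYH11-A
D	1	2	CBFB-MYH11-A
D	1	3	CBFB-MYH11-A
D	2	1	CBFB-MYH11-D
D	2	2	CBFB-MYH11-D
D	2	3	CBFB-MYH11-D
D	3	1	CBFB-MYH11-E
D	3	2	CBFB-MYH11-E
D	3	3	CBFB-MYH11-E
D	4	1	CBFB
D	4	2	CBFB
D	4	3	CBFB
D	5	1	MYH11-A
D	5	2	MYH11-A
D	5	3	MYH11-A
D	6	1	MYH11-DE
D	6	2	MYH11-DE
D	6	3	MYH11-DE
E	0	1	BIOTIN
E	1	1	AF9
E	1	2	AF9
E	1	3	AF9
E	2	1	ENL
E	2	2	ENL
E	2	3	ENL
E	3	1	ELL
E	3	2	ELL
E	3	3	ELL
E	4	1	AF6
E	4	2	AF6
E	4	3	AF6
E	5	1	AF10-A
E	5	2	AF10-A
E	5	3	AF10-A
E	6	1	AF10-B
E	6	2	AF10-B
E	6	3	AF10-B
F	0	1	BIOTIN
F	1	1	MLL
F	1	2	MLL
F	1	3	MLL
F	2	1	AF4
F	2	2	AF4
F	2	3	AF4
F	3	1	BLANK
F	3	2	BLANK
F	3	3	BLANK
F	4	1	BLANK
F	4	2	BLANK
F	4	3	BLANK
F	5	1	BLANK
F	5	2	BLANK
F	5	3	BLANK
F	6	1	BLANK
F	6	2	BLANK
F	6	3	BLANK
G	0	1	BIOTIN
G	1	1	TEL-AML1ex2
G	1	2	TEL-AML1ex2
G	1	3	TEL-AML1ex2
G	2	1	TEL-AML1ex3
G	2	2	TEL-AML1ex3
G	2	3	TEL-AML1ex3
G	3	1	TEL
G	3	2	TEL
G	3	3	TEL
G	4	1	AML1ex3
G	4	2	AML1ex3
G	4	3	AML1ex3
G	5	1	BLANK
G	5	2	BLANK
G	5	3	BLANK
G	6	1	BLANK
G	6	2	BLANK
G	6	3	BLANK
H	0	1	BIOTIN
H	1	1	E2A-PBX1-I
H	1	2	E2A-PBX1-I
H	1	3	E2A-PBX1-I
H	2	1	E2A-PBX1-Ia
H	2	2	E2A-PBX1-Ia
H	2	3	E2A-PBX1-Ia
H	3	1	E2A
H	3	2	E2A
H	3	3	E2A
H	4	1	PBX1
H	4	2	PBX1
H	4	3	PBX1
H	5	1	BLANK
H	5	2	BLANK
H	5	3	BLANK
H	6	1	BLANK
H	6	2	BLANK
H	6	3	BLANK
I	0	1	BIOTIN
I	1	1	SIL-TAL1-I
I	1	2	SIL-TAL1-I
I	1	3	SIL-TAL1-I
I	2	1	SIL-TAL1-II
I	2	2	SIL-TAL1-II
I	2	3	SIL-TAL1-II
I	3	1	SIL-TAL1-III
I	3	2	SIL-TAL1-III
I	3	3	SIL-TAL1-III
I	4	1	SIL
I	4	2	SIL
I	4	3	SIL
I	5	1	TAL1
I	5	2	TAL1
I	5	3	TAL1
I	6	1	BLANK
I	6	2	BLANK
I	6	3	BLANK
J	0	1	BIOTIN
J	1	1	p190
J	1	2	p190
J	1	3	p190
J	2	1	BCR190
J	2	2	BCR190
J	2	3	BCR190
J	3	1	BLANK
J	3	2	BLANK
J	3	3	BLANK
J	4	1	BLANK
J	4	2	BLANK
J	4	3	BLANK
J	5	1	BLANK
J	5	2	BLANK
J	5	3	BLANK
J	6	1	BLANK
J	6	2	BLANK
J	6	3	BLANK
K	0	1	BIOTIN
K	1	1	p210-b2a2
K	1	2	p210-b2a2
K	1	3	p210-b2a2
K	2	1	p210-b3a2
K	2	2	p210-b3a2
K	2	3	p210-b3a2
K	3	1	BCR210
K	3	2	BCR210
K	3	3	BCR210
K	4	1	p230
K	4	2	p230
K	4	3	p230
K	5	1	BCR230
K	5	2	BCR230
K	5	3	BCR230
K	6	1	ABL
K	6	2	ABL
K	6	3	ABL
L	0	1	BIOTIN
L	1	1	GUS
L	1	2	GUS
L	1	3	GUS
L	2	1	BLANK
L	2	2	BLANK
L	2	3	BLANK
L	3	1	GUS
L	3	2	GUS
L	3	3	GUS
L	4	1	BLANK
L	4	2	BLANK
L	4	3	BLANK
L	5	1	GUS
L	5	2	GUS
L	5	3	GUS
L	6	1	BLANK
L	6	2	BLANK
L	6	3	BLANK
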