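index	smarts	min_count	description
0	[#3,#11,#19,#37,#55]	1	alkali metal
1	[#8]	1	oxygen present
2	[#4,#12,#20,#38,#56]	1	alkaline-earth metal
3	[#8]	2	two or more oxygens
4	[#21,#22,#23,#24,#25]	1	early transition metal (Sc-Mn)
5	[#8]	3	three or more oxygens
6	[#26,#27,#28]	1	iron-group metal (Fe, Co, Ni)
7	[#8]	4	four or more oxygens
8	[#29,#30]	1	copper or zinc
9	[#7]	1	nitrogen present
10	[#42,#47,#48]	1	second-row transition metal (Mo, Ag, Cd)
11	[#7]	2	two or more nitrogens
12	[#78,#79,#80]	1	platinum-group or heavy metal (Pt, Au, Hg)
13	[#7]	3	three or more nitrogens
14	[#13]	1	aluminium
15	[#16]	1	sulfur present
16	[#50,#82]	1	tin or lead
17	[#16]	2	two or more sulfurs
18	[#14]	1	silicon
19	[#6]	8	eight or more carbons
20	[#5]	1	boron
21	[#6]	12	twelve or more carbons
22	[#32,#33,#34]	1	germanium, arsenic or selenium
23	[!#6;!#1]	1	heteroatom present
24	[#9]	1	fluorine
25	[!#6;!#1]	3	three or more heteroatoms
26	[#17]	1	chlorine
27	[CH3]	1	methyl group
28	[#35]	1	bromine
29	[CH3]	2	two or more methyl groups
30	[#53]	1	iodine
31	[CH3]	3	three or more methyl groups
32	[F,Cl,Br,I]	1	any halogen
33	[CX4H2]	1	methylene group
34	[F,Cl,Br,I]	2	two or more halogens
35	[CX4H2]	4	four or more methylene groups
36	[#15]	1	phosphorus
37	[CX4H1]	1	methine carbon
38	[#15]=[#8]	1	phosphoryl P=O
39	[CX4H0]	1	quaternary sp3 carbon
40	[#15](~[#8])(~[#8])~[#8]	1	phosphate-like phosphorus
41	[OX2H]	1	hydroxyl group
42	[#14][#8]	1	silicon-oxygen bond
43	[OX2H]	2	two or more hydroxyl groups
44	[#5][#8]	1	boron-oxygen bond
45	[NX3;H2]	1	primary amine N
46	[#6][#17]	1	carbon-chlorine bond
47	[NX3;H1]	1	N-H secondary nitrogen
48	[#6][#35]	1	carbon-bromine bond
49	[SX2H]	1	thiol group
50	[#6][#53]	1	carbon-iodine bond
51	[CX3]=[CX3]	1	carbon-carbon double bond
52	[#6][#9]	1	carbon-fluorine bond
53	[CX3]=[CX3]	2	two or more C=C double bonds
54	[CX2]#[NX1]	1	nitrile group
55	[CX3]=[NX2]	1	imine C=N
56	[NX2]=[NX2]	1	azo group
57	[!#6;!#1;R]	1	heteroatom in ring
59	[NX3][NX3]	1	hydrazine-like N-N bond
60	[NX3][OX2]	1	nitrogen-oxygen single bond
62	c1ccccc1	1	benzene ring
63	[OX2][OX2]	1	peroxide O-O
64	[#16]=[#8]	1	sulfur-oxygen double bond
65	[n]	1	aromatic nitrogen
66	[SX4](=[OX1])=[OX1]	1	sulfonyl group
68	[SX4](=[OX1])(=[OX1])[NX3]	1	sulfonamide
69	[SX2]([#6])[#6]	1	thioether sulfur
71	[SX2][SX2]	1	disulfide bond
72	[CX3]=[SX1]	1	thiocarbonyl C=S
74	[CX3]=[OX1]	1	carbonyl group
75	[CX3]=[OX1]	2	two or more carbonyl groups
76	[CX3H1]=[OX1]	1	aldehyde group
77	[#6][CX3](=[OX1])[#6]	1	ketone group
78	[CX3](=[OX1])[OX2H]	1	carboxylic acid group
80	[NX3;H2]	2	two or more primary amines
81	[CX3](=[OX1])[OX2H0][#6]	1	ester group
82	[NX3][CX3](=[OX1])[NX3]	1	urea group
83	[NX3][CX3](=[OX1])[OX2]	1	carbamate group
84	[CX3](=[OX1])[OX2][CX3]=[OX1]	1	acid anhydride
86	C#C	1	carbon-carbon triple bond
87	[CX4]([OX2])[OX2]	1	gem-dioxy carbon (acetal-like)
88	[OX2H0]([#6])[#6]	1	ether oxygen
89	[R]	1	ring atom present
90	[R]	6	six or more ring atoms
92	[r3]	1	three-membered ring
93	[r4]	1	four-membered ring
94	[r5]	1	five-membered ring
95	[r6]	1	six-membered ring
96	[r7]	1	seven-membered ring
98	[$([#8;R]),$([#16;R])]	1	oxygen or sulfur in ring
99	[R2]	1	ring-fusion atom
100	[R2]	2	fused ring system
101	[#7;R]	1	nitrogen in ring
102	[#8;R]	1	oxygen in ring
104	[#16;R]	1	sulfur in ring
105	[CX3;R]=[OX1]	1	cyclic carbonyl
106	a	1	aromatic atom present
107	a	6	six or more aromatic atoms
108	c1ccccc1	2	two or more benzene rings
110	[o]	1	aromatic oxygen
111	[s]	1	aromatic sulfur
112	[nX3]	1	pyrrole-type aromatic nitrogen
113	[a;!c]	1	heteroaromatic atom
114	c[OX2H]	1	phenolic hydroxyl
116	c[OX2H0]	1	aromatic ether oxygen
117	c[CX3]=[OX1]	1	carbonyl on aromatic ring
118	c[CH3]	1	methyl on aromatic ring
119	c[CX3]=[CX3]	1	vinyl on aromatic ring
120	c-c	1	biaryl single bond
122	[NX3][CX3]=[OX1]	1	amide group
123	[CX4][CX4][CX4]	1	three-carbon sp3 chain
124	[CX4H1]([CH3])[CH3]	1	isopropyl group
125	[CX4]([CH3])([CH3])[CH3]	1	tert-butyl group
126	[CX3]=[NX2][OX2H]	1	oxime group
128	[NX3][CX3](=[NX2])[NX3]	1	guanidine group
130	[OX2][CX3]=[CX3]	1	enol ether
131	[CX3]=[CX3][CX3]=[CX3]	1	conjugated diene
132	[OX2r3]	1	epoxide oxygen
133	[NX3r3]	1	aziridine nitrogen
134	[CX3;R](=[OX1])[OX2;R]	1	lactone
135	[CX3;R](=[OX1])[NX3;R]	1	lactam
136	[$([NX3](=O)=O),$([NX3+](=O)[O-])]	1	nitro group
137	[OX1]=[CX3]1[CX3]=[CX3][CX3](=[OX1])[CX3]=[CX3]1	1	para-quinone motif
138	[+]	1	positively charged atom
139	[-]	1	negatively charged atom
140	[CX4]	1	sp3 carbon present
141	[CX4]	6	six or more sp3 carbons
142	[nX2]	1	pyridine-type aromatic nitrogen
143	[#7][#6][#8]	1	N-C-O unit
144	a	10	ten or more aromatic atoms
145	[#7]	4	four or more nitrogens
146	[!#6;!#1]	5	five or more heteroatoms
147	[CH3][CX4H2]	1	ethyl group
148	[OX2]	2	two or more divalent oxygens
149	[#6]=[#6][#6]=[OX1]	1	carbonyl conjugated to C=C
150	[aR2]	2	fused aromatic ring system
151	[NX3]([CX4])[CX4]	1	dialkyl nitrogen
152	[OX2H][CX4][CX4][NX3]	1	beta-amino alcohol motif
153	[#7]~[#8]	1	any nitrogen-oxygen bond
154	[#6]1[#6][#6][#6][#6][#6]1	1	cyclohexane-type ring
155	[CX4;R]	1	sp3 ring carbon
156	[cH0]	3	three or more substituted aromatic carbons
157	[CH3][OX2]	1	methoxy-like group
158	[#7][CX3]=[OX1]	1	nitrogen on carbonyl carbon
159	[OX2H][#6][#6][OX2H]	1	1,2-diol motif
160	[CH3]	4	four or more methyl groups
161	[#7]	1	nitrogen present (duplicate family key)
162	a	1	aromatic system present (duplicate family key)
163	[r6]	2	two or more six-membered rings
164	[#8]~[#6]~[#7]	1	O-C-N any-bond unit
58	c[F,Cl,Br,I]	1	halogen on aromatic ring
61	[CX4]([F,Cl,Br,I])[F,Cl,Br,I]	1	geminal dihalide carbon
67	[#40,#41,#72,#73,#74]	1	refractory transition metal (Zr, Nb, Hf, Ta, W)
70	[#44,#45,#46]	1	platinum-group metal (Ru, Rh, Pd)
73	[#57,#58,#59,#60,#62,#63,#64]	1	lanthanide metal
79	[#90,#92]	1	actinide metal (Th, U)
85	[#3]	1	lithium
91	[#11]	1	sodium
97	[#19]	1	potassium
103	[#12]	1	magnesium
109	[#20]	1	calcium
115	[#26]	1	iron
121	[#30]	1	zinc
127	[#29]	1	copper
129	[#25]	1	manganese
165	[#24]	1	chromium
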