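# public 166-bit structural key dictionary, version v1
# columns: key <TAB> smarts <TAB> min_count <TAB> comment
# bit k is set when the SMARTS attains at least min_count unique matches
# '@'-prefixed patterns are computed handlers, not SMARTS
1	@none	1	isotope key; not evaluated, always 0
2	[#104]	1	
3	[#32,#33,#34,#50,#51,#52,#82,#83,#84]	1	
4	[Ac,Th,Pa,U,Np,Pu,Am,Cm,Bk,Cf,Es,Fm,Md,No,Lr]	1	
5	[Sc,Ti,Y,Zr,Hf]	1	
6	[La,Ce,Pr,Nd,Pm,Sm,Eu,Gd,Tb,Dy,Ho,Er,Tm,Yb,Lu]	1	
7	[V,Cr,Mn,Nb,Mo,Tc,Ta,W,Re]	1	
8	[!#6;!#1]1~*~*~*~1	1	
9	[Fe,Co,Ni,Ru,Rh,Pd,Os,Ir,Pt]	1	
10	[Be,Mg,Ca,Sr,Ba,Ra]	1	
11	*1~*~*~*~1	1	
12	[Cu,Zn,Ag,Cd,Au,Hg]	1	
13	[#8]~[#7](~[#6])~[#6]	1	
14	[#16]-[#16]	1	
15	[#8]~[#6](~[#8])~[#8]	1	
16	[!#6;!#1]1~*~*~1	1	
17	[#6]#[#6]	1	
18	[#5,#13,#31,#49,#81]	1	
19	*1~*~*~*~*~*~*~1	1	
20	[#14]	1	
21	[#6]=[#6](~[!#6;!#1])~[!#6;!#1]	1	
22	*1~*~*~1	1	
23	[#7]~[#6](~[#8])~[#8]	1	
24	[#7]-[#8]	1	
25	[#7]~[#6](~[#7])~[#7]	1	
26	[#6]=;@[#6](@*)@*	1	
27	[I]	1	
28	[!#6;!#1]~[CH2]~[!#6;!#1]	1	
29	[#15]	1	
30	[#6]~[!#6;!#1](~[#6])(~[#6])~*	1	
31	[!#6;!#1]~[F,Cl,Br,I]	1	
32	[#6]~[#16]~[#7]	1	
33	[#7]~[#16]	1	
34	[CH2]=*	1	
35	[Li,Na,K,Rb,Cs,Fr]	1	
36	[#16R]	1	
37	[#7]~[#6](~[#8])~[#7]	1	
38	[#7]~[#6](~[#6])~[#7]	1	
39	[#8]~[#16](~[#8])~[#8]	1	
40	[#16]-[#8]	1	
41	[#6]#[#7]	1	
42	F	1	
43	[!#6;!#1;!H0]~*~[!#6;!#1;!H0]	1	
44	[!#1;!#6;!#7;!#8;!#9;!#14;!#15;!#16;!#17;!#35;!#53]	1	
45	[#6]=[#6]~[#7]	1	
46	Br	1	
47	[#16]~*~[#7]	1	
48	[#8]~[!#6;!#1](~[#8])(~[#8])	1	
49	[!+0]	1	
50	[#6]=[#6](~[#6])~[#6]	1	
51	[#6]~[#16]~[#8]	1	
52	[#7]~[#7]	1	
53	[!#6;!#1;!H0]~*~*~*~[!#6;!#1;!H0]	1	
54	[!#6;!#1;!H0]~*~*~[!#6;!#1;!H0]	1	
55	[#8]~[#16]~[#8]	1	
56	[#8]~[#7](~[#8])~[#6]	1	
57	[#8R]	1	
58	[!#6;!#1]~[#16]~[!#6;!#1]	1	
59	[#16]!:*:*	1	
60	[#16]=[#8]	1	
61	*~[#16](~*)~*	1	
62	*@*!@*@*	1	
63	[#7]=[#8]	1	
64	*@*!@[#16]	1	
65	c:n	1	
66	[#6]~[#6](~[#6])(~[#6])~*	1	
67	[!#6;!#1]~[#16]	1	
68	[!#6;!#1;!H0]~[!#6;!#1;!H0]	1	
69	[!#6;!#1]~[!#6;!#1;!H0]	1	
70	[!#6;!#1]~[#7]~[!#6;!#1]	1	
71	[#7]~[#8]	1	
72	[#8]~*~*~[#8]	1	
73	[#16]=*	1	
74	[CH3]~*~[CH3]	1	
75	*!@[#7]@*	1	
76	[#6]=[#6](~*)~*	1	
77	[#7]~*~[#7]	1	
78	[#6]=[#7]	1	
79	[#7]~*~*~[#7]	1	
80	[#7]~*~*~*~[#7]	1	
81	[#16]~*(~*)~*	1	
82	*~[CH2]~[!#6;!#1;!H0]	1	
83	[!#6;!#1]1~*~*~*~*~1	1	
84	[NH2]	1	
85	[#6]~[#7](~[#6])~[#6]	1	
86	[C;H2,H3][!#6;!#1][C;H2,H3]	1	
87	[F,Cl,Br,I]!@*@*	1	
88	[#16]	1	
89	[#8]~*~*~*~[#8]	1	
90	[$([!#6;!#1;!H0]~*~*~[CH2]~*),$([!#6;!#1;!H0;R]1@[R]@[R]@[CH2;R]1),$([!#6;!#1;!H0]~[R]1@[R]@[CH2;R]1)]	1	
91	[$([!#6;!#1;!H0]~*~*~*~[CH2]~*),$([!#6;!#1;!H0;R]1@[R]@[R]@[R]@[CH2;R]1),$([!#6;!#1;!H0]~[R]1@[R]@[R]@[CH2;R]1),$([!#6;!#1;!H0]~*~[R]1@[R]@[CH2;R]1)]	1	
92	[#8]~[#6](~[#7])~[#6]	1	
93	[!#6;!#1]~[CH3]	1	
94	[!#6;!#1]~[#7]	1	
95	[#7]~*~*~[#8]	1	
96	*1~*~*~*~*~1	1	
97	[#7]~*~*~*~[#8]	1	
98	[!#6;!#1]1~*~*~*~*~*~1	1	
99	[#6]=[#6]	1	
100	*~[CH2]~[#7]	1	
101	[$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1),$([R]@1@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]@[R]1)]	1	
102	[!#6;!#1]~[#8]	1	
103	Cl	1	
104	[!#6;!#1;!H0]~*~[CH2]~*	1	
105	*@*(@*)@*	1	
106	[!#6;!#1]~*(~[!#6;!#1])~[!#6;!#1]	1	
107	[F,Cl,Br,I]~*(~*)~*	1	
108	[CH3]~*~*~*~[CH2]~*	1	
109	*~[CH2]~[#8]	1	
110	[#7]~[#6]~[#8]	1	
111	[#7]~*~[CH2]~*	1	
112	*~*(~*)(~*)~*	1	
113	[#8]!:*:*	1	
114	[CH3]~[CH2]~*	1	
115	[CH3]~*~[CH2]~*	1	
116	[$([CH3]~*~*~[CH2]~*),$([CH3]~*1~*~[CH2]1)]	1	
117	[#7]~*~[#8]	1	
118	[$(*~[CH2]~[CH2]~*),$(*1~[CH2]~[CH2]1)]	2	
119	[#7]=*	1	
120	[!#6;R]	2	
121	[#7;R]	1	
122	*~[#7](~*)~*	1	
123	[#8]~[#6]~[#8]	1	
124	[!#6;!#1]~[!#6;!#1]	1	
125	@aromatic_ring_count	2	two or more aromatic rings; computed from ring perception
126	*!@[#8]!@*	1	
127	*@*!@[#8]	2	
128	[$(*~[CH2]~*~*~*~[CH2]~*),$([R]1@[CH2;R]@[R]@[R]@[R]@[CH2;R]1),$(*~[CH2]~[R]1@[R]@[R]@[CH2;R]1),$(*~[CH2]~*~[R]1@[R]@[CH2;R]1)]	1	
129	[$(*~[CH2]~*~*~[CH2]~*),$([R]1@[CH2]@[R]@[R]@[CH2;R]1),$(*~[CH2]~[R]1@[R]@[CH2;R]1)]	1	
130	[!#6;!#1]~[!#6;!#1]	2	
131	[!#6;!#1;!H0]	2	
132	[#8]~*~[CH2]~*	1	
133	*@*!@[#7]	1	
134	[F,Cl,Br,I]	1	
135	[#7]!:*:*	1	
136	[#8]=*	2	
137	[!C;!c;R]	1	
138	[!#6;!#1]~[CH2]~*	2	
139	[O;!H0]	1	
140	[#8]	4	
141	[CH3]	3	
142	[#7]	2	
143	*@*!@[#8]	1	
144	*!:*:*!:*	1	
145	*1~*~*~*~*~*~1	2	
146	[#8]	3	
147	[$(*~[CH2]~[CH2]~*),$([R]1@[CH2;R]@[CH2;R]1)]	1	
148	*~[!#6;!#1](~*)~*	1	
149	[C;H3,H4]	2	
150	*!@*@*!@*	1	
151	[#7;!H0]	1	
152	[#8]~[#6](~[#6])~[#6]	1	
153	[!#6;!#1]~[CH2]~*	1	
154	[#6]=[#8]	1	
155	*!@[CH2]!@*	1	
156	[#7]~*(~*)~*	1	
157	[#6]-[#8]	1	
158	[#6]-[#7]	1	
159	[#8]	2	
160	[C;H3,H4]	1	
161	[#7]	1	
162	a	1	
163	*1~*~*~*~*~*~1	1	
164	[#8]	1	
165	[R]	1	
166	@fragment_count	2	two or more covalent fragments; computed from connectivity
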