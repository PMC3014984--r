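# template: bp4helix102
index	segment	role	value
1	ncap	FIXED	M
2	ncap	FIXED	G
3	ncap	FIXED	S
4	ncap	FIXED	D
5	helix1	FIXED	D
6	helix1	FIXED	A
7	helix1	COMBINATORIAL	POLAR
8	helix1	COMBINATORIAL	NONPOLAR
9	helix1	COMBINATORIAL	POLAR
10	helix1	COMBINATORIAL	POLAR
11	helix1	COMBINATORIAL	NONPOLAR
12	helix1	COMBINATORIAL	NONPOLAR
13	helix1	COMBINATORIAL	POLAR
14	helix1	COMBINATORIAL	POLAR
15	helix1	COMBINATORIAL	NONPOLAR
16	helix1	COMBINATORIAL	POLAR
17	helix1	COMBINATORIAL	POLAR
18	helix1	COMBINATORIAL	NONPOLAR
19	helix1	COMBINATORIAL	NONPOLAR
20	helix1	COMBINATORIAL	POLAR
21	helix1	COMBINATORIAL	POLAR
22	helix1	FIXED	K
23	helix1	FIXED	G
24	turn1	FIXED	G
25	turn1	COMBINATORIAL	TURN
26	turn1	COMBINATORIAL	TURN
27	turn1	COMBINATORIAL	TURN
28	turn1	COMBINATORIAL	TURN
29	turn1	FIXED	G
30	helix2	FIXED	D
31	helix2	FIXED	A
32	helix2	COMBINATORIAL	POLAR
33	helix2	COMBINATORIAL	POLAR
34	helix2	COMBINATORIAL	NONPOLAR
35	helix2	COMBINATORIAL	NONPOLAR
36	helix2	COMBINATORIAL	POLAR
37	helix2	COMBINATORIAL	POLAR
38	helix2	COMBINATORIAL	NONPOLAR
39	helix2	COMBINATORIAL	POLAR
40	helix2	COMBINATORIAL	POLAR
41	helix2	COMBINATORIAL	NONPOLAR
42	helix2	COMBINATORIAL	NONPOLAR
43	helix2	COMBINATORIAL	POLAR
44	helix2	COMBINATORIAL	POLAR
45	helix2	FIXED	K
46	helix2	FIXED	G
47	turn2	FIXED	G
48	turn2	COMBINATORIAL	TURN
49	turn2	COMBINATORIAL	TURN
50	turn2	COMBINATORIAL	TURN
51	turn2	COMBINATORIAL	TURN
52	turn2	FIXED	G
53	helix3	FIXED	D
54	helix3	FIXED	A
55	helix3	COMBINATORIAL	POLAR
56	helix3	COMBINATORIAL	NONPOLAR
57	helix3	COMBINATORIAL	POLAR
58	helix3	COMBINATORIAL	POLAR
59	helix3	COMBINATORIAL	NONPOLAR
60	helix3	COMBINATORIAL	NONPOLAR
61	helix3	COMBINATORIAL	POLAR
62	helix3	COMBINATORIAL	POLAR
63	helix3	COMBINATORIAL	NONPOLAR
64	helix3	COMBINATORIAL	POLAR
65	helix3	COMBINATORIAL	POLAR
66	helix3	COMBINATORIAL	NONPOLAR
67	helix3	COMBINATORIAL	NONPOLAR
68	helix3	COMBINATORIAL	POLAR
69	helix3	COMBINATORIAL	POLAR
70	helix3	FIXED	K
71	helix3	FIXED	G
72	turn3	FIXED	G
73	turn3	COMBINATORIAL	TURN
74	turn3	COMBINATORIAL	TURN
75	turn3	COMBINATORIAL	TURN
76	turn3	COMBINATORIAL	TURN
77	turn3	FIXED	G
78	helix4	FIXED	D
79	helix4	FIXED	A
80	helix4	COMBINATORIAL	POLAR
81	helix4	COMBINATORIAL	POLAR
82	helix4	COMBINATORIAL	NONPOLAR
83	helix4	COMBINATORIAL	NONPOLAR
84	helix4	COMBINATORIAL	POLAR
85	helix4	COMBINATORIAL	POLAR
86	helix4	COMBINATORIAL	NONPOLAR
87	helix4	COMBINATORIAL	POLAR
88	helix4	COMBINATORIAL	POLAR
89	helix4	COMBINATORIAL	NONPOLAR
90	helix4	COMBINATORIAL	NONPOLAR
91	helix4	COMBINATORIAL	POLAR
92	helix4	COMBINATORIAL	POLAR
93	helix4	FIXED	K
94	helix4	FIXED	G
95	ccap	FIXED	G
96	ccap	FIXED	S
97	ccap	FIXED	R
98	ccap	FIXED	E
99	ccap	FIXED	L
100	ccap	FIXED	Q
101	ccap	FIXED	K
102	ccap	FIXED	N
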