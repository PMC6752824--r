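K_r	category	label	K_cat
1	cancer	Lung cancer	1
2	cancer	Breast cancer	2
3	cancer	Leukemia	3
4	cancer	Prostate cancer	4
5	cancer	Colorectal cancer	5
6	cancer	Brain tumor	6
7	cancer	Pancreatic cancer	7
8	cancer	Melanoma	8
9	cancer	Stomach cancer	9
10	cancer	Ovarian cancer	10
11	cancer	Cervical cancer	11
12	cancer	Hodgkin lymphoma	12
13	cancer	Skin cancer	13
14	drug	Talc	1
15	cancer	Multiple myeloma	14
16	cancer	Esophageal cancer	15
17	cancer	Liver cancer	16
18	cancer	Non-Hodgkin lymphoma	17
19	cancer	Bladder cancer	18
20	drug	Methotrexate	2
21	cancer	Head and neck cancer	19
22	drug	Thalidomide	3
23	cancer	Testicular cancer	20
24	drug	Paclitaxel	4
25	drug	Prednisone	5
26	drug	Cisplatin	6
27	drug	Dexamethasone	7
28	cancer	Thyroid cancer	21
29	drug	Doxorubicin	8
30	cancer	Bone tumor	22
31	drug	Propranolol	9
32	drug	Interleukin 2	10
33	cancer	Kidney cancer	23
34	cancer	Mesothelioma	24
35	drug	Cyclophosphamide	11
36	drug	Fluorouracil	12
37	cancer	Oral cancer	25
38	drug	Tamoxifen	13
39	drug	Vincristine	14
40	drug	Rituximab	15
41	drug	Bevacizumab	16
42	drug	HPV vaccines	17
43	drug	Imatinib	18
44	drug	Arsenic trioxide	19
45	cancer	Uterine cancer	26
46	drug	Dactinomycin	20
47	cancer	Cholangiocarcinoma	27
48	drug	Ondansetron	21
49	drug	Trastuzumab	22
50	drug	Vinblastine	23
51	cancer	Neuroendocrine tumor	28
52	drug	Bleomycin	24
53	drug	Carboplatin	25
54	drug	Mercaptopurine	26
55	drug	Docetaxel	27
56	drug	Daunorubicin	28
57	drug	Hyaluronidase	29
58	drug	Etoposide	30
59	drug	Bortezomib	31
60	drug	Irinotecan	32
61	cancer	Soft-tissue sarcoma	29
62	drug	Oxaliplatin	33
63	drug	Melphalan	34
64	drug	Leuprorelin	35
65	drug	Raloxifene	36
66	drug	Hydroxycarbamide	37
67	drug	Aminolevulinic acid	38
68	drug	Cytarabine	39
69	drug	Cetuximab	40
70	drug	Folinic acid	41
71	drug	Mitomycin C	42
72	cancer	Anal cancer	30
73	drug	Gemcitabine	43
74	drug	Sorafenib	44
75	drug	Imiquimod	45
76	cancer	Spinal tumor	31
77	drug	Sunitinib	46
78	drug	Ifosfamide	47
79	drug	Erlotinib	48
80	drug	Asparaginase	49
81	drug	Gefitinib	50
82	cancer	Gestational trophoblastic disease	32
83	drug	Anastrozole	51
84	drug	Epirubicin	52
85	drug	Lenalidomide	53
86	drug	Capecitabine	54
87	drug	Vorinostat	55
88	drug	Chlormethine	56
89	drug	Everolimus	57
90	drug	Alemtuzumab	58
91	drug	Chlorambucil	59
92	drug	Filgrastim	60
93	drug	Goserelin	61
94	drug	Ipilimumab	62
95	drug	Temozolomide	63
96	drug	Peginterferon	64
97	drug	Mitoxantrone	65
98	cancer	Gallbladder cancer	33
99	drug	Vemurafenib	66
100	drug	Topotecan	67
101	drug	Fludarabine	68
102	drug	Pembrolizumab	69
103	drug	Tioguanine	70
104	drug	Dacarbazine	71
105	drug	Azacitidine	72
106	cancer	Vaginal cancer	34
107	drug	Carmustine	73
108	drug	Decitabine	74
109	drug	Bicalutamide	75
110	drug	Flutamide	76
111	cancer	Vulvar cancer	35
112	drug	Procarbazine	77
113	drug	Cladribine	78
114	drug	Tocilizumab	79
115	drug	Busulfan	80
116	drug	Denosumab	81
117	drug	Pemetrexed	82
118	drug	Lomustine	83
119	drug	Vinorelbine	84
120	drug	Nivolumab	85
121	drug	Dabrafenib	86
122	drug	Letrozole	87
123	drug	Fulvestrant	88
124	drug	Radium-223	89
125	drug	Olaparib	90
126	drug	Pazopanib	91
127	drug	Dasatinib	92
128	drug	Idarubicin	93
129	drug	Temsirolimus	94
130	drug	Exemestane	95
131	drug	Crizotinib	96
132	drug	Zoledronic acid	97
133	drug	Panobinostat	98
134	drug	Mesna	99
135	drug	Ibritumomab tiuxetan	100
136	drug	Trametinib	101
137	drug	Nilotinib	102
138	drug	Ixabepilone	103
139	drug	Megestrol acetate	104
140	drug	Romiplostim	105
141	drug	Afatinib	106
142	drug	ThioTEPA	107
143	drug	Aprepitant	108
144	drug	Aflibercept	109
145	drug	Eribulin	110
146	drug	Panitumumab	111
147	drug	Ofatumumab	112
148	cancer	Adrenal tumor	36
149	drug	Sipuleucel-T	113
150	drug	Pamidronic acid	114
151	drug	Cabozantinib	115
152	drug	Brentuximab vedotin	116
153	drug	Gemtuzumab ozogamicin	117
154	drug	Enzalutamide	118
155	drug	Pegfilgrastim	119
156	drug	Romidepsin	120
157	drug	Rasburicase	121
158	drug	Bendamustine	122
159	drug	Interferon alfa-2b	123
160	drug	Obinutuzumab	124
161	drug	Denileukin diftitox	125
162	drug	Ruxolitinib	126
163	drug	Talimogene laherparepvec	127
164	drug	Belinostat	128
165	drug	Eltrombopag	129
166	drug	Cabazitaxel	130
167	drug	Lanreotide	131
168	drug	Palbociclib	132
169	drug	Pomalidomide	133
170	drug	Trastuzumab emtansine	134
171	drug	Vismodegib	135
172	cancer	Appendix cancer	37
173	drug	Omacetaxine mepesuccinate	136
174	drug	Plerixafor	137
175	drug	Lapatinib	138
176	drug	Clofarabine	139
177	drug	Vandetanib	140
178	drug	Axitinib	141
179	drug	Ibrutinib	142
180	drug	Methylnaltrexone	143
181	drug	Carfilzomib	144
182	drug	Protein-bound paclitaxel	145
183	drug	Bosutinib	146
184	drug	Ceritinib	147
185	drug	Abiraterone acetate	148
186	drug	Trabectedin	149
187	drug	Elotuzumab	150
188	drug	Nelarabine	151
189	drug	Palonosetron	152
190	drug	Cobimetinib	153
191	drug	Amifostine	154
192	drug	Atezolizumab	155
193	drug	Ixazomib	156
194	drug	Lenvatinib	157
195	drug	Trifluridine	158
196	drug	Ponatinib	159
197	drug	Alectinib	160
198	drug	Nilutamide	161
199	drug	Daratumumab	162
200	drug	Valrubicin	163
201	drug	Sonidegib	164
202	drug	Osimertinib	165
203	drug	Pertuzumab	166
204	drug	Defibrotide	167
205	drug	Bexarotene	168
206	drug	Palifermin	169
207	drug	Idelalisib	170
208	drug	Toremifene	171
209	drug	Apalutamide	172
210	drug	Regorafenib	173
211	drug	Venetoclax	174
212	drug	Dexrazoxane	175
213	drug	Avelumab	176
214	drug	Dinutuximab	177
215	drug	Ramucirumab	178
216	drug	Blinatumomab	179
217	drug	Rolapitant	180
218	drug	Niraparib	181
219	drug	Pralatrexate	182
220	drug	Acalabrutinib	183
221	drug	Brigatinib	184
222	drug	Necitumumab	185
223	drug	Midostaurin	186
224	drug	Rucaparib	187
225	drug	Inotuzumab ozogamicin	188
226	drug	Pegaspargase	189
227	drug	Durvalumab	190
228	drug	Siltuximab	191
229	drug	Ribociclib	192
230	drug	Degarelix	193
231	drug	Neratinib	194
232	drug	Abemaciclib	195
233	drug	Olaratumab	196
234	drug	Copanlisib	197
235	drug	Netupitant/palonosetron	198
236	drug	Tipiracil	199
237	drug	Uridine triacetate	200
238	drug	Axicabtagene ciloleucel	201
239	drug	Glucarpidase	202
240	drug	Tisagenlecleucel	203
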