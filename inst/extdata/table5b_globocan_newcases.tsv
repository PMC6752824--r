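rank	label	value	units
1	Lung cancer	2093.9	newcases_2018_thousands
2	Breast cancer	2088.8	newcases_2018_thousands
3	Colorectal cancer	1801.0	newcases_2018_thousands
4	Prostate cancer	1276.1	newcases_2018_thousands
5	Skin cancer	1042.1	newcases_2018_thousands
6	Stomach cancer	1033.7	newcases_2018_thousands
7	Head and neck cancer	887.7	newcases_2018_thousands
8	Liver cancer	841.1	newcases_2018_thousands
9	Esophageal cancer	572.0	newcases_2018_thousands
10	Cervical cancer	569.8	newcases_2018_thousands
11	Thyroid cancer	567.2	newcases_2018_thousands
12	Bladder cancer	549.4	newcases_2018_thousands
13	Non-Hodgkin lymphoma	509.6	newcases_2018_thousands
14	Pancreatic cancer	458.9	newcases_2018_thousands
15	Leukemia	437.0	newcases_2018_thousands
16	Kidney cancer	403.3	newcases_2018_thousands
17	Uterine cancer	382.1	newcases_2018_thousands
18	Brain tumor	296.9	newcases_2018_thousands
19	Ovarian cancer	295.4	newcases_2018_thousands
20	Melanoma	287.7	newcases_2018_thousands
21	Gallbladder cancer	219.4	newcases_2018_thousands
22	Multiple myeloma	160.0	newcases_2018_thousands
23	Hodgkin lymphoma	80.0	newcases_2018_thousands
24	Testicular cancer	71.1	newcases_2018_thousands
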