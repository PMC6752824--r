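rank	label	value	units
1	Lung cancer	40900	dalys_2017_thousands
2	Liver cancer	20800	dalys_2017_thousands
3	Stomach cancer	19100	dalys_2017_thousands
4	Colorectal cancer	19000	dalys_2017_thousands
5	Breast cancer	17700	dalys_2017_thousands
6	Leukemia	12000	dalys_2017_thousands
7	Head and neck cancer	10600	dalys_2017_thousands
8	Esophageal cancer	9780	dalys_2017_thousands
9	Pancreatic cancer	9080	dalys_2017_thousands
10	Brain tumor	8740	dalys_2017_thousands
11	Cervical cancer	8060	dalys_2017_thousands
12	Prostate cancer	7060	dalys_2017_thousands
13	Non-Hodgkin lymphoma	7020	dalys_2017_thousands
14	Ovarian cancer	4670	dalys_2017_thousands
15	Bladder cancer	3600	dalys_2017_thousands
16	Gallbladder cancer	3480	dalys_2017_thousands
17	Kidney cancer	3280	dalys_2017_thousands
18	Skin cancer	2980	dalys_2017_thousands
19	Multiple myeloma	2330	dalys_2017_thousands
20	Uterine cancer	2140	dalys_2017_thousands
21	Hodgkin lymphoma	1380	dalys_2017_thousands
22	Thyroid cancer	1130	dalys_2017_thousands
23	Mesothelioma	671	dalys_2017_thousands
24	Testicular cancer	375	dalys_2017_thousands
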