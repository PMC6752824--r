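rank	label	value	units
1	Lung cancer	1883.1	deaths_2017_thousands
2	Colorectal cancer	896.0	deaths_2017_thousands
3	Stomach cancer	865.0	deaths_2017_thousands
4	Liver cancer	819.4	deaths_2017_thousands
5	Breast cancer	611.6	deaths_2017_thousands
6	Pancreatic cancer	441.1	deaths_2017_thousands
7	Esophageal cancer	436.0	deaths_2017_thousands
8	Prostate cancer	415.9	deaths_2017_thousands
9	Head and neck cancer	380.6	deaths_2017_thousands
10	Leukemia	347.6	deaths_2017_thousands
11	Cervical cancer	259.7	deaths_2017_thousands
12	Non-Hodgkin lymphoma	248.6	deaths_2017_thousands
13	Brain tumor	247.1	deaths_2017_thousands
14	Bladder cancer	196.5	deaths_2017_thousands
15	Ovarian cancer	176.0	deaths_2017_thousands
16	Gallbladder cancer	174.0	deaths_2017_thousands
17	Kidney cancer	138.5	deaths_2017_thousands
18	Skin cancer	126.8	deaths_2017_thousands
19	Multiple myeloma	107.1	deaths_2017_thousands
20	Uterine cancer	85.2	deaths_2017_thousands
21	Thyroid cancer	41.2	deaths_2017_thousands
22	Hodgkin lymphoma	32.6	deaths_2017_thousands
23	Mesothelioma	29.9	deaths_2017_thousands
24	Testicular cancer	7.7	deaths_2017_thousands
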