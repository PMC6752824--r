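rank	label	value	units
1	Lung cancer	1761.0	deaths_2018_thousands
2	Colorectal cancer	861.7	deaths_2018_thousands
3	Stomach cancer	782.7	deaths_2018_thousands
4	Liver cancer	781.6	deaths_2018_thousands
5	Breast cancer	626.7	deaths_2018_thousands
6	Esophageal cancer	508.6	deaths_2018_thousands
7	Head and neck cancer	453.3	deaths_2018_thousands
8	Pancreatic cancer	432.2	deaths_2018_thousands
9	Prostate cancer	359.0	deaths_2018_thousands
10	Cervical cancer	311.4	deaths_2018_thousands
11	Leukemia	309.0	deaths_2018_thousands
12	Non-Hodgkin lymphoma	248.7	deaths_2018_thousands
13	Brain tumor	241.0	deaths_2018_thousands
14	Bladder cancer	199.9	deaths_2018_thousands
15	Ovarian cancer	184.8	deaths_2018_thousands
16	Kidney cancer	175.1	deaths_2018_thousands
17	Gallbladder cancer	165.1	deaths_2018_thousands
18	Multiple myeloma	106.1	deaths_2018_thousands
19	Uterine cancer	89.9	deaths_2018_thousands
20	Skin cancer	65.2	deaths_2018_thousands
21	Melanoma	60.7	deaths_2018_thousands
22	Thyroid cancer	41.1	deaths_2018_thousands
23	Hodgkin lymphoma	26.2	deaths_2018_thousands
24	Mesothelioma	25.6	deaths_2018_thousands
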