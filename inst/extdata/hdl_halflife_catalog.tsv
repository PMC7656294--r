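accession	protein	control_thalf	control_sd	hfd_thalf	hfd_sd	significant_printed
Q546G4	Albumin	76.93	7.49	66.09	6.13	1
P29699	Alpha-2-HS-glycoprotein	20.92	1.60	15.92	2.74	1
A0A0A6YWH7	Antithrombin-III (fragment)	24.77	2.13	18.34	1.16	1
Q3V2G1	Apolipoprotein A-I	24.33	1.76	20.51	1.64	1
Q6LD55	Apolipoprotein A-II	15.43	0.69	15.09	1.68	0
Q6LAL7	Beta-2-glycoprotein 1	30.88	3.46	20.75	4.67	1
Q9DBB9	Carboxypeptidase N subunit 2	30.14	2.26	26.60	2.00	1
P01027	Complement C3	12.77	0.81	9.98	1.20	1
Q3UEG8	Complement Factor B	12.71	1.01	10.85	1.04	0
D6RGQ0	Complement Factor H	19.60	1.84	16.80	1.58	1
Q61129	Complement Factor I	25.25	1.29	19.88	1.50	1
Q91X72	Hemopexin	39.82	6.57	39.92	9.65	0
A0A0R4J039	Histidine-rich Glycoprotein	23.63	1.99	19.28	2.83	1
A0A0R4J038	Kininogen-1	25.09	1.59	21.18	0.91	1
P28665	Murinoglobulin-1	39.67	3.22	32.08	1.73	1
Q3V1T9	Plasminogen	22.04	1.25	15.45	3.42	1
Q61838	Pregnancy Zone Protein	41.71	3.50	38.91	2.29	0
Q07456	Protein AMBP	14.23	1.97	13.21	1.09	0
Q3TJ94	Prothrombin	27.20	6.04	21.87	4.66	1
Q921I1	Serotransferrin	37.62	1.74	33.12	6.63	1
P21614	Vitamin D-binding Protein	13.48	0.50	10.00	0.84	1
G3X8Q5	Ceruloplasmin	27.10	6.12	18.55	3.41	1
P34928	Apolipoprotein C-I	17.66	6.52	10.39	8.06	0
P33622	Apolipoprotein C-III	10.16	1.57	11.30	2.18	0
P08226	Apolipoprotein E	10.50	5.53	8.09	1.95	0
A2A997	Complement component C8 Alpha Chain	26.50	2.22	19.24	3.85	1
Q9QWK4	CD5 Antigen-Like	32.66	8.35	28.42	3.43	0
Q8BH35	Complement component C8 beta chain	24.51	4.68	18.83	1.95	1
Q9EP98	Epidermal growth factor receptor	38.05	3.82	27.58	3.90	1
P03953	Complement Factor D	20.06	1.19	16.71	0.61	1
A0A075B5P6	Ig mu chain C region (fragments)	44.95	8.23	35.34	11.15	0
Q9DBD0	Inhibitor of Carbonic Anhydrase	18.24	1.36	13.52	0.41	1
P29788	Vitronectin	15.71	2.27	11.95	0.88	1
E9PV24	Fibrinogen alpha chain	40.15	7.35	41.78	3.03	0
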