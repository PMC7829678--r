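region_id	region_name	network	x	y	z
15	MFG_L_7_1	ECN	-27	43	31
16	MFG_R_7_1	ECN	30	37	36
17	MFG_L_7_2	ECN	-42	13	36
18	MFG_R_7_2	ECN	42	11	39
23	MFG_L_7_5	ECN	-33	23	45
26	MFG_R_7_6	ECN	34	8	54
132	SPL_R_5_4	FPN	23	-43	67
136	IPL_R_6_1	DMN	45	-71	20
138	IPL_R_6_2	DMN	39	-65	44
142	IPL_R_6_4	DMN	57	-44	38
143	IPL_L_6_5	DMN	-47	-65	26
144	IPL_R_6_5	DMN	53	-54	25
151	Pcun_L_4_3	DMN	-12	-67	25
152	Pcun_R_4_3	DMN	16	-64	25
153	Pcun_L_4_4	DMN	-6	-55	34
154	Pcun_R_4_4	DMN	6	-54	35
161	PoG_L_4_4	DAN	-21	-35	68
175	CG_L_7_1	DMN	-4	-39	31
176	CG_R_7_1	DMN	4	-37	32
181	CG_L_7_4	DMN	-8	-47	10
182	CG_R_7_4	DMN	9	-44	11
183	CG_L_7_5	DMN	-45	7	37
209	sOcG_L_2_2	VN	-22	-77	36
210	sOcG_R_2_2	VN	29	-75	36
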