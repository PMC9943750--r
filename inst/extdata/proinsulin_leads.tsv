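locus	marker	chr	pos	ea	nea	eaf	beta	se	p	group
SIX3	rs12712928	2	45192080	C	G	0.16	0.09	0.01	1.5e-21	primary
ELAPOR1	rs74920406	1	109704525	C	T	0.96	0.15	0.02	3.7e-16	primary
TLE1	rs2796441	9	84308948	G	A	0.59	0.05	0.01	9.6e-14	primary
TPD52	rs1346146	8	81047278	T	C	0.45	0.05	0.01	2.0e-13	primary
GIPR	rs10423928	19	46182304	A	T	0.22	0.06	0.01	7.6e-12	primary
STX16	rs218473	20	57235980	C	T	0.32	0.05	0.01	1.5e-10	primary
DLC1	rs2977105	8	12794444	C	T	0.82	0.06	0.01	1.0e-09	primary
FAM46C	rs826415	1	118153977	T	G	0.67	0.04	0.01	1.3e-09	primary
PCSK2	rs111925767	20	17331621	T	G	0.23	0.05	0.01	1.6e-09	primary
RNF6	rs10507349	13	26781528	G	A	0.78	0.05	0.01	1.9e-09	primary
PAM	rs75457267	5	102658770	C	T	0.96	0.10	0.02	2.2e-09	primary
SLC7A14	rs56252324	3	170334547	A	C	0.87	0.06	0.01	5.4e-09	primary
WIPI1	rs2302783	17	66447073	C	T	0.72	0.04	0.01	1.1e-08	primary
NKX6-3/ANK1	rs13266210	8	41533514	G	A	0.21	0.05	0.01	2.1e-08	primary
FAM185A	rs10228495	7	102440184	C	T	0.45	0.04	0.01	2.9e-08	primary
JARID2	rs16876519	6	15496122	A	G	0.85	0.05	0.01	3.5e-08	primary
STARD10	rs77464186	11	72460398	C	A	0.19	0.26	0.01	3.7e-202	previously_reported
MADD	rs10501320	11	47293799	G	C	0.76	0.21	0.01	1.3e-165	previously_reported
PCSK1	rs13169290	5	95729406	A	G	0.28	0.12	0.01	3.3e-59	previously_reported
CDC4A/B	rs11856307	15	62399093	A	C	0.54	0.09	0.01	6.4e-40	previously_reported
TCF7L2	rs7903146	10	114758349	T	C	0.26	0.10	0.01	1.9e-39	previously_reported
SLC30A8	rs4300038	8	118217915	G	A	0.66	0.09	0.01	4.1e-39	previously_reported
LARP6	rs113350503	15	71111437	G	A	0.57	0.06	0.01	6.5e-18	previously_reported
DDX31	rs368476	9	135456552	A	G	0.65	0.07	0.01	7.6e-21	previously_reported
SNX7	rs6702126	1	99199954	G	A	0.65	0.04	0.01	8.7e-10	previously_reported
SGSM2	rs61741902	17	2282779	A	G	0.01	0.47	0.03	5.8e-49	previously_reported
TBC1D30	rs150781447	12	65224220	T	C	0.02	0.30	0.04	9.1e-17	previously_reported
KANK1	rs146375546	9	727176	G	A	0.03	0.26	0.04	4.3e-11	previously_reported
SLC2A10	rs3091537	20	45332200	A	C	0.64	0.04	0.01	3.9e-08	bmi_unadjusted
BCL11A	rs243018	2	60586707	G	C	0.45	0.04	0.01	2.4e-08	bmi_unadjusted
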