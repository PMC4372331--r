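comparison	class_a	class_b	gene_symbol	chrom	pos	ref_allele	alt_allele	carriers_a	n_a	carriers_b	n_b	dbsnp_id	aa_change	domain	or_printed	p_printed
ER	ER-	ER+	SLC24A1	chr15	65916527	A	T	23	27	13	40	rs3743171	p.T37S	PfamB PB047652	11.94	2.11E-05
ER	ER-	ER+	CSN3	chr4	71114956	G	T	15	27	7	40	rs1048152	p.R110L	Kappa casein	5.89	1.59E-03
ER	ER-	ER+	ERBB2	chr17	37884037	C	G	8	27	26	40	rs1058808	p.P1140A	PfamB PB015832	0.23	6.24E-03
ER	ER-	ER+	PPP2R4	chr9	131909736	C	T	11	27	2	40	rs2480452	p.S287L	PTPA protein	13.06	4.29E-04
ER	ER-	ER+	DPP3	chr11	66276576	G	A	7	27	28	40	rs12421620	p.E690K	Peptidase family M49	0.15	1.41E-03
ER	ER-	ER+	KRT74	chr12	52966428	G	C	12	27	5	40	rs11170177	p.N165K	Intermediate filament	5.60	4.53E-03
ER	ER-	ER+	GPR157	chr1	9165685	G	A	5	27	24	40	rs72637739	p.R218C	Secretin receptor family	0.15	1.01E-03
ER	ER-	ER+	FAM209B	chr20	55111364	A	C	12	27	4	40	rs2296129	p.E129A	FAM209 family	7.20	2.63E-03
PR	PR-	PR+	KIAA1377	chr11	101832590	C	A	15	30	4	37	rs11225089	p.S275Y	Monomelic amyotrophy	8.25	7.84E-04
PR	PR-	PR+	CPN1	chr10	101829514	C	T	10	30	1	37	rs61751507	p.G178D	Peptidase_M14	18.00	1.57E-03
PR	PR-	PR+	RBM46	chr4	155719189	T	G	8	30	0	37	rs79167802	p.I126M	RRM_1	NA	8.97E-04
PR	PR-	PR+	DPP3	chr11	66276576	G	A	9	30	26	37	rs12421620	p.E690K	Peptidase family M49	0.18	1.41E-03
PR	PR-	PR+	HKR1	chr19	37854040	G	A	12	30	4	37	rs2921563	p.R448H	zf-H2C2_2	5.50	8.63E-03
HER2	HER2-	HER2+	CENPJ	chr13	25486911	G	T	5	42	4	8	rs9511510	p.P85T	PfamB PB003077	0.14	2.64E-02
HER2	HER2-	HER2+	GABRE	chrX	151138179	A	C	40	42	4	8	rs1139916	p.S102A	Neurotransmitter-gated ion channel	20.00	3.94E-03
HER2	HER2-	HER2+	SP4	chr7	21469504	C	G	3	42	4	8	rs139491266	p.L241V	PfamB PB022696	0.08	8.54E-03
Grade	GradeII	GradeIII	ANKRD32	chr5	94030818	G	T	0	25	4	13	rs76504036	p.C993F	PfamB PB101142	0.00	9.69E-03
Grade	GradeII	GradeIII	GFM2	chr5	74037386	T	A	2	25	5	13	rs16872235	p.S300C	GTP_EFTU	0.14	3.41E-02
Stage	StageII	StageIII	LPPR2	chr19	11473358	C	G	1	70	5	18	rs11540666	p.T253S	PAP2 superfamily	0.04	1.14E-03
Stage	StageII	StageIII	PRCP	chr11	82564294	T	G	5	70	8	18	rs2229437	p.E112D	Serine carboxypeptidase S28	0.10	4.80E-04
Stage	StageII	StageIII	GSTO1	chr10	106022789	C	A	13	70	11	18	rs4925	p.A140D	GST C-terminal	0.15	7.33E-04
Stage	StageII	StageIII	PLEKHG6	chr12	6421495	G	A	26	70	15	18	rs740842	p.A35T	PfamB PB015161	0.12	5.23E-04
Stage	StageII	StageIII	AGL	chr1	100358103	C	T	5	70	5	18	rs3753494	p.P1051S	Amylo-alpha-1,6-glucosidase	0.20	2.72E-02
Stage	StageII	StageIII	AGL	chr1	100361925	G	A	20	70	10	18	rs2230307	p.G1115R	Amylo-alpha-1,6-glucosidase	0.32	4.93E-02
Stage	StageII	StageIII	MMP20	chr11	102482504	T	G	3	70	5	18	rs17099008	p.I169L	Peptidase_M10	0.12	8.03E-03
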