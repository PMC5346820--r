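rank	name	description	degree	betweenness	closeness	disease_score
1	TP53	tumor protein p53	89	0.13	0.72	1.98
2	EGFR	epidermal growth factor receptor	71	0.05	0.65	1.50
3	ALB	Albumin	69	0.05	0.64	0.88
4	ERBB2	v-erb-b2 erythroblastic leukemia viral oncogene homolog 2, neuro/glioblastoma derived oncogene homolog (avian)	69	0.07	0.65	1.99
5	AKT1	v-akt murine thymoma viral oncogene homolog 1	65	0.05	0.63	1.23
6	SRC	v-src sarcoma (Schmidt-Ruppin A-2) viral oncogene homolog (avian)	64	0.06	0.61	1.25
7	CDH1	cadherin 1, type 1, E-cadherin (epithelial)	64	0.02	0.62	2.09
8	KRAS	v-Ki-ras2 Kirsten rat sarcoma viral oncogene homolog	63	0.02	0.62	0.86
9	CTNNB1	catenin (cadherin-associated protein), beta 1, 88kDa	61	0.03	0.63	1.69
10	HRAS	v-Ha-ras Harvey rat sarcoma viral oncogene homolog	60	0.02	0.61	0.96
11	CCND1	cyclin D1	59	0.04	0.61	1.29
12	MYC	v-myc myelocytomatosis viral oncogene homolog (avian)	59	0.04	0.61	1.49
13	PTEN	phosphatase and tensin homolog	55	0.02	0.58	0.97
14	VEGFA	vascular endothelial growth factor A	53	0.01	0.58	1.41
15	MMP9	matrix metallopeptidase 9 (gelatinase B, 92kDa gelatinase, 92kDa type IV collagenase)	50	0.02	0.58	1.21
16	STAT3	signal transducer and activator of transcription 3 (acute-phase response factor)	50	0.01	0.56	0.96
17	TGFB1	transforming growth factor, beta 1	49	0.01	0.56	0.99
18	CDKN2A	cyclin-dependent kinase inhibitor 2A	48	0.02	0.58	1.34
19	TNF	tumor necrosis factor	47	0.02	0.56	0.97
20	KIT	v-kit Hardy-Zuckerman 4 feline sarcoma viral oncogene homolog	46	0.01	0.55	0.91
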