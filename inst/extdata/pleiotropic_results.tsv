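snp	nearest_gene	distance	context	class	stratum	direction
rs12678919	LPL	19452	intergenic	HDL Cholesterol	NHW	+
rs12678919	LPL	19452	intergenic	Triglycerides	NHW	+
rs562338	APOB	21376	intergenic	Cholesterol	NHW	-
rs562338	APOB	21376	intergenic	Hearing	NHB	+
rs174547	FADS1	0	intron	Ferritin	MA	+
rs174547	FADS1	0	intron	Folate	NHB	-
rs174547	FADS1	0	intron	Triglycerides	NHW	-
rs2338104	KCTD10	0	intron	Hearing	NHW	+
rs2338104	KCTD10	0	intron	Hemoglobin	NHW	-
rs780094	GCKR	0	intron	Glucose	MA	+
rs780094	GCKR	0	intron	Potassium intake	MA	-
rs780094	GCKR	0	intron	Vitamin B6 intake	MA	-
rs6855911	SLC2A9	0	intron	Kidney (Uric Acid)	MA	-
rs6855911	SLC2A9	0	intron	Kidney (Uric Acid)	NHB	-
rs6855911	SLC2A9	0	intron	Body measurements	NHB	+
rs646776	CELSR2	152	nearGene-3	Cholesterol	MA	-
rs646776	CELSR2	152	nearGene-3	Cholesterol	NHB	-
rs646776	CELSR2	152	nearGene-3	Cholesterol	NHW	-
rs646776	CELSR2	152	nearGene-3	LDL Cholesterol	MA	-
rs964184	ZNF259	359	nearGene-3	Cholesterol	MA	+
rs964184	ZNF259	359	nearGene-3	Cholesterol	NHW	+
rs964184	ZNF259	359	nearGene-3	Triglycerides	MA	+
rs964184	ZNF259	359	nearGene-3	Triglycerides	NHW	+
rs964184	ZNF259	359	nearGene-3	Vitamin E	MA	+
rs964184	ZNF259	359	nearGene-3	Vitamin E	NHW	+
rs1800588	LIPC	500	nearGene-5	Cholesterol	NHW	+
rs1800588	LIPC	500	nearGene-5	Folate	MA	-
rs1800588	LIPC	500	nearGene-5	Triglycerides	NHW	+
rs1800588	LIPC	500	nearGene-5	Vitamin E	NHW	+
rs2231142	ABCG2	0	STOP-GAIN	Blood Pressure (Diastolic)	MA	+
rs2231142	ABCG2	0	STOP-GAIN	Kidney (Uric Acid)	MA	-
rs2231142	ABCG2	0	STOP-GAIN	Kidney (Uric Acid)	NHW	-
rs2231142	ABCG2	0	STOP-GAIN	Protoporphyrin	MA	-
rs2231142	ABCG2	0	STOP-GAIN	Protoporphyrin	NHW	-
rs328	LPL	0	STOP-GAIN	HDL Cholesterol	MA	+
rs328	LPL	0	STOP-GAIN	HDL Cholesterol	NHW	+
rs328	LPL	0	STOP-GAIN	Triglycerides	NHW	-
rs12740374	CELSR2	0	UTR-3	Cholesterol	MA	-
rs12740374	CELSR2	0	UTR-3	Cholesterol	NHB	-
rs12740374	CELSR2	0	UTR-3	Cholesterol	NHW	-
rs12740374	CELSR2	0	UTR-3	LDL Cholesterol	MA	-
rs12740374	CELSR2	0	UTR-3	LDL Cholesterol	NHB	-
rs28927680	BUD13	0	UTR-3	Triglycerides	MA	-
rs28927680	BUD13	0	UTR-3	Triglycerides	NHW	-
rs28927680	BUD13	0	UTR-3	Vitamin E	NHW	-
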