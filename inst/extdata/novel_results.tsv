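gene	snp	chrom	pos	coded_allele	class	stratum	survey	phenotype	transform	p	beta	se	n
BSND-PCSK9	rs11206510	1	55496039	T	Globulin	MA	survey1	Serum globulin (g/dL)	ln1p	0.0095	0.012	0.0046	2023
BSND-PCSK9	rs11206510	1	55496039	T	Globulin	MA	survey2	Globulin (g/L)	ln1p	0.0042	0.012	0.0062	1871
GCKR	rs1260326	2	27730940	T	Vitamin A	NHW	survey1	Vitamin A (ug/dL)	none	0.0061	1.3	0.47	2550
GCKR	rs1260326	2	27730940	T	Vitamin A	NHW	survey2	Vitamin A (ug/dL)	none	0.00011	2.34	0.61	1639
SLC30A8	rs13266634	8	118184783	T	Vitamin E	NHW	survey1	Vitamin E (ug/dL)	none	0.005	-50.23	17.86	2595
SLC30A8	rs13266634	8	118184783	T	Vitamin E	NHW	survey2	Vitamin E (umol/L)	none	0.0037	-1.7	0.58	1627
FADS1	rs174547	11	61570783	T	Ferritin	MA	survey1	Ferritin (ng/mL)	ln1p	0.005	0.11	0.037	1826
FADS1	rs174547	11	61570783	T	Ferritin	MA	survey2	Ferritin (ug/L)	ln1p	0.0089	0.1	0.04	1861
FADS1	rs174547	11	61570783	T	Folate	NHB	survey1	RBC folate (ng/mL)	none	0.00015	-15.14	3.98	2028
FADS1	rs174547	11	61570783	T	Folate	NHB	survey2	Folate, serum (nmol/L)	none	0.0013	-4.54	1.41	1330
LIPC	rs1800588	15	58723675	T	Folate	MA	survey1	Serum folate (ng/mL)	none	0.0089	-0.32	0.12	1996
LIPC	rs1800588	15	58723675	T	Folate	MA	survey2	Folate, RBC (nmol/L RBC)	ln1p	0.0001	-0.047	0.012	1838
LIPC	rs1800588	15	58723675	T	Vitamin E	NHW	survey1	Vitamin E (ug/dL)	ln1p	0.00059	0.044	0.013	2553
LIPC	rs1800588	15	58723675	T	Vitamin E	NHW	survey2	Vitamin E (umol/L)	ln1p	0.00065	0.06	0.017	1609
ABCG2	rs2231142	4	89052323	C	Blood Pressure (Diastolic)	MA	survey1	Overall average K5, diastolic BP	ln1p	1.45e-06	0.033	0.0068	2023
ABCG2	rs2231142	4	89052323	C	Blood Pressure (Diastolic)	MA	survey2	Diastolic: Blood pres (3rd rdg) mm Hg	none	0.0045	1.69	0.59	1605
ABCG2	rs2231142	4	89052323	C	Protoporphyrin	MA	survey1	Protoporphyrin (ug/dL RBC)	ln1p	2.61e-07	-0.075	0.015	2029
ABCG2	rs2231142	4	89052323	C	Protoporphyrin	MA	survey2	Protoporphyrin (ug/dL RBC)	ln1p	0.0002	-0.079	0.021	968
ABCG2	rs2231142	4	89052323	C	Protoporphyrin	NHW	survey1	Protoporphyrin (ug/dL RBC)	ln1p	6e-06	-0.062	0.014	2587
ABCG2	rs2231142	4	89052323	C	Protoporphyrin	NHW	survey2	Protoporphyrin (ug/dL RBC)	ln1p	0.00066	-0.06	0.01	1667
KCTD10	rs2338104	12	109895168	G	Hearing	NHW	survey1	Right Threshold @ 1000Hz-Second Reading	none	0.0034	2.2	0.74	258
KCTD10	rs2338104	12	109895168	G	Hearing	NHW	survey2	Right threshold @ 500Hz	none	0.006	1.11	0.4	1415
KCTD10	rs2338104	12	109895168	G	Hemoglobin	NHW	survey1	Mean cell hemoglobin: SI (pg)	ln1p	0.0016	-0.005	0.0016	2582
KCTD10	rs2338104	12	109895168	G	Hemoglobin	NHW	survey2	Mean cell hemoglobin (pg)	ln1p	0.0018	-0.0042	0.0013	3964
BUD13	rs28927680	11	116619073	G	Vitamin E	NHW	survey1	Vitamin E (ug/dL)	ln1p	4.45e-05	-0.086	0.021	2596
BUD13	rs28927680	11	116619073	G	Vitamin E	NHW	survey2	Vitamin E (umol/L)	ln1p	0.001	-0.09	0.027	1624
TNFRSF11B	rs4355801	8	119923873	G	White Blood Cell	NHB	survey1	White blood cell count: SI	none	0.0036	0.3	0.1	2077
TNFRSF11B	rs4355801	8	119923873	G	White Blood Cell	NHB	survey2	White blood cell count SI	none	0.0079	0.378	0.14	1334
SLC2A9	rs6855911	4	9935910	G	Body Measurements (Leg)	NHB	survey1	Thigh circumference (cm)	none	0.0012	0.8	0.25	1972
SLC2A9	rs6855911	4	9935910	G	Body Measurements (Leg)	NHB	survey2	Thigh Circumference (cm)	none	0.0061	0.89	0.33	1256
APOB-KLHL29	rs562338	2	21288321	T	Hearing	NHB	survey1	Left ear air hear level, repeat, 1000Hz (dB)	ln1p	0.0071	0.2	0.075	377
APOB-KLHL29	rs562338	2	21288321	T	Hearing	NHB	survey2	Left threshold @ 1000Hz (db)	none	0.0096	1.99	0.77	528
GCKR	rs780094	2	27741237	G	Potassium intake	MA	survey1	Potassium (mg)	none	0.0043	-132.98	0.66	1961
GCKR	rs780094	2	27741237	G	Potassium intake	MA	survey2	Potassium (mg)	none	0.0047	-139.47	0.67	1798
GCKR	rs780094	2	27741237	G	Vitamin B6 intake	MA	survey1	Vitamin B6 (mg)	none	0.0098	-0.1	0.66	1961
GCKR	rs780094	2	27741237	G	Vitamin B6 intake	MA	survey2	Vitamin B6 (mg)	none	0.0042	-0.11274	0.67	1798
IL6	rs1800795	7	22766645	G	White Blood Cell Count	NHB	survey1	White blood cell count: SI	none	0.0047	-0.34	0.12	2038
IL6	rs1800795	7	22766645	G	White Blood Cell Count	NHB	survey2	Segmented Neutrophils number	ln1p	0.0048	-0.071	0.025	1316
KCNQ1	rs2237895	11	2857194	C	Body Measurement (Arm)	MA	survey1	Arm circumference (cm)	none	0.0019	-0.47	0.15	1987
KCNQ1	rs2237895	11	2857194	C	Body Measurement (Arm)	MA	survey2	Upper Arm Length (cm)	ln1p	0.0061	-0.0062	0.0022	1835
none	rs1529729	19	11163562	G	Broken/Fractured Bone	NHW	survey1	Doctor told had broken/fractured spine	none	0.0042	0.493	0.25	2303
none	rs1529729	19	11163562	G	Broken/Fractured Bone	NHW	survey2	Broken or fractured spine	ln1p	0.002	1.54	0.14	3933
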