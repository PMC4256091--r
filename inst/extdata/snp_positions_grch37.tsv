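snp	chrom	pos	context
rs12678919	8	19844222	intergenic
rs328	8	19813529	STOP-GAIN
rs2231142	4	89052323	STOP-GAIN
rs6855911	4	9935910	intron
rs7442295	4	9998662	intron
rs1800588	15	58723675	nearGene-5
rs646776	1	109818530	nearGene-3
rs12740374	1	109817590	UTR-3
rs174547	11	61570783	intron
rs3135506	11	116662407	missense
rs780094	2	27741237	intron
rs2338104	12	109895168	intron
rs28927680	11	116619073	UTR-3
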