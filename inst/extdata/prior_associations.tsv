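snp	prior_class	related_group	direction	source
rs646776	LDL Cholesterol	lipids	-	19060906
rs646776	Cholesterol	lipids	-	19198609
rs515135	LDL Cholesterol	lipids		19060906
rs7557067	Triglycerides	lipids		18193043
rs11206510	LDL Cholesterol	lipids		19198609
rs11206510	Coronary heart disease			20864672
rs11206510	Myocardial infarction			18193043
rs2231142	Kidney (Uric Acid)	urate	-	22229870
rs6855911	Kidney (Uric Acid)	urate	-	17997608
rs1800588	HDL Cholesterol	lipids		18193044
rs1260326	Triglycerides	lipids	+	18454146
rs1260326	Cholesterol	lipids	+	20657596
rs12678919	HDL Cholesterol	lipids		19060906
rs12678919	Triglycerides	lipids		19060906
rs328	HDL Cholesterol	lipids		18193044
rs328	Triglycerides	lipids		18193044
rs2338104	HDL Cholesterol	lipids		19060906
rs28927680	Triglycerides	lipids		18193044
rs964184	Cholesterol	lipids		20864672
rs964184	Triglycerides	lipids		20864672
rs964184	Vitamin E levels			20864672
rs12740374	LDL Cholesterol	lipids		19060906
rs562338	LDL Cholesterol	lipids		19060906
rs780094	Triglycerides	lipids		18439548
rs4355801	Bone mineral density			18455228
rs1800795	Inflammation (C-reactive protein)			15820616
rs13266634	Diabetes			17460697
rs174547	HDL Cholesterol	lipids		20639392
rs174547	Triglycerides	lipids		19060906
rs2237895	Diabetes			20174558
rs1529729	LDL Cholesterol	lipids		18714375
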