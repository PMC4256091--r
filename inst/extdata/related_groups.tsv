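class	group
Cholesterol	lipids
LDL Cholesterol	lipids
HDL Cholesterol	lipids
Triglycerides	lipids
Lipoprotein	lipids
Apolipoprotein	lipids
High Cholesterol	lipids
Kidney (Uric Acid)	urate
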