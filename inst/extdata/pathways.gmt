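TGF_beta_receptor_pathway	NetPath	LPL	FADS1
urate_metabolic_process	GO	ABCG2	SLC2A9
glycerolipid_metabolism	KEGG	LPL	LIPC
PPAR_signaling_pathway	KEGG	LPL	APOA5
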