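chrom	start	end	symbol
1	109792641	109818378	CELSR2
2	27719709	27746551	GCKR
4	89011416	89052548	ABCG2
4	9771153	10054936	SLC2A9
8	19796764	19824770	LPL
11	61567099	61584475	FADS1
11	116617256	116633896	BUD13
11	116660086	116663136	APOA5
12	109880841	109914462	KCTD10
15	58724175	58861073	LIPC
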