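variantId	geneId	tssDistance	maf	eqtlLog10P	nInformativeSamples	medianReads
var1	gene1	1000	0.3	-10	150	57
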