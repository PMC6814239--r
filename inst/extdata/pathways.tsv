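pathway	gene
Pathways in cancer	APC
Pathways in cancer	BRAF
Pathways in cancer	BRCA2
Pathways in cancer	KRAS
Pathways in cancer	MLH1
Pathways in cancer	PTEN
Pathways in cancer	RB1
Pathways in cancer	RET
Pathways in cancer	STK11
Pathways in cancer	TP53
Pathways in cancer	VHL
Mismatch repair	MLH1
Mismatch repair	MSH2
Mismatch repair	MSH6
Mismatch repair	PMS2
Homologous recombination	ATM
Homologous recombination	BRCA1
Homologous recombination	BRCA2
Homologous recombination	PALB2
Homologous recombination	RAD51
Thyroid cancer	BRAF
Thyroid cancer	RET
Thyroid cancer	TP53
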