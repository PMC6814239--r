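# Genes with a low rate of benign missense variation (PP2).
CACNA1A
FBN1
KCNQ2
MECP2
PTPN11
SCN1A
SCN2A
SMAD3
TP53
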