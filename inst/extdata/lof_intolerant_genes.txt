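# Genes with an established loss-of-function disease mechanism (PVS1).
# Curated default list; replace with a cohort-appropriate table as needed.
APC
ATM
BRCA1
BRCA2
CDH1
CHEK2
DMD
MEN1
MLH1
MSH2
MSH6
NF1
NF2
PALB2
PMS2
PTEN
RB1
SMAD4
STK11
TP53
TSC1
TSC2
VHL
WT1
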