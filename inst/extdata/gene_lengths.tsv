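gene	coding_kb
TTN	100.2
MUC16	43.5
OBSCN	24.3
SYNE1	26.2
NEB	20.3
USH2A	15.6
AHNAK	17.4
BRCA2	10.3
APC	8.5
ATM	9.2
DMD	11.1
BRCA1	5.6
MLH1	2.3
TP53	1.2
RET	3.3
ALDH2	1.6
OR4F5	0.9
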