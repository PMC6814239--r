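gene	protein_pos	ref_aa	alt_aa
TP53	175	R	H
TP53	248	R	W
TP53	273	R	H
KRAS	12	G	D
KRAS	12	G	V
BRAF	600	V	E
RET	918	M	T
FBN1	1796	C	Y
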