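# Protein domains without established pathogenic missense variation
# (suppress PM1).
Zinc_finger_C2H2
Collagen_triple_helix_repeat
Mucin-like_glycoprotein
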