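# Genes where truncating variants are the primary disease mechanism,
# making missense changes less likely pathogenic (BP1).
APC
DMD
NEB
TTN
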