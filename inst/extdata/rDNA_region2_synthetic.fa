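>rDNA_region2_synthetic
AATGATCGTCATCGATCTCGTACTCGAATTCGTCATCGATCTCGTACTCGAATTCGTCATCGATCTCGTACTCGAATTCG
TCATTAATTCGATCTCGTACTCGAATTCGTCATCGATCTCGTACTCGAATTCGTCATCGATCTCGTACTCGAATTCGTCA
TTAGATT
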