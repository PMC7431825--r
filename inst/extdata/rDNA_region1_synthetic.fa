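>rDNA_region1_synthetic
AATGATCGTCATCGATCTCGTACTCGAATTCGTCATCGATCTCGTACTCGAATTCGTCATCGATCTCGTACTCGAATTCG
TCATCGATCTCGTACTCGAATTCGTCATCGATCTCGTACTTAATTCGAATTCGTCATCGATCTCGTACTCGAATTCGTCA
TCGATCTCGTACTCGAATTCGTCATCGATCTCGTACTCGAATTCGTCATCGATCTCGTACTCGAATTCGTCATCGATCTT
AGATT
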