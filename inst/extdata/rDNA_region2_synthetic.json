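{
  "name": "rDNA_region2_synthetic",
  "region": "UCE+promoter",
  "cpg_positions": [7, 13, 19, 25, 31, 37, 43, 49, 55, 61, 67, 73, 79, 90, 96, 102, 108, 114, 120, 126, 132, 138, 144, 150, 156],
  "variant_position": 87
}
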