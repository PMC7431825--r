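{
  "name": "rDNA_region1_synthetic",
  "region": "ETS",
  "cpg_positions": [7, 13, 19, 25, 31, 37, 43, 49, 55, 61, 67, 73, 79, 85, 91, 97, 103, 109, 115, 126, 132, 138, 144, 150, 156, 162, 168, 174, 180, 186, 192, 198, 204, 210, 216, 222, 228, 234],
  "variant_position": 123
}
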