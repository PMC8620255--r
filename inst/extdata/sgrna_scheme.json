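{
  "name": "t7_engen",
  "promoter": "TTCTAATACGACTCACTATAG",
  "overlap": "GTTTTAGAGCTAGA",
  "require_leading_g": false,
  "note": "T7 promoter appended 5' of the 20-nt target site and 14-nt scaffold-overlap appended 3', as in standard T7 in-vitro sgRNA transcription kits."
}
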