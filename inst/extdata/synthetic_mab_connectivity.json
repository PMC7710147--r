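[
  {"chain_a": "SYNH", "pos_a": 6,  "chain_b": "SYNL", "pos_b": 5},
  {"chain_a": "SYNH", "pos_a": 14, "chain_b": "SYNL", "pos_b": 13},
  {"chain_a": "SYNH", "pos_a": 25, "chain_b": "SYNH", "pos_b": 28}
]
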