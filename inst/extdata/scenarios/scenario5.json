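{
  "id": 5,
  "comment": "Scenario 1 plus ongoing restocking from Iberia throughout (present to t3).",
  "populations": ["Iber", "Col", "TXL", "SNP", "AMR"],
  "generation_length_years": 5,
  "sizes": {"Iber": "Ne_Iber", "Col": "Ne_Col", "TXL": "Ne_TXL", "SNP": "Ne_SNP", "AMR": "Ne_ANC"},
  "splits": [
    {"time": "t1", "derived": "Col", "ancestral": "AMR"},
    {"time": "t1", "derived": "SNP", "ancestral": "AMR"},
    {"time": "t2", "derived": "TXL", "ancestral": "AMR"},
    {"time": "t3", "derived": "AMR", "ancestral": "Iber"}
  ],
  "migration": [
    {"from": ["Col", "TXL", "SNP", "AMR"], "to": "Iber", "start": 0, "end": "t3", "rate": "m"}
  ]
}
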