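{
  "id": 3,
  "comment": "Scenario 1 plus recent restocking from Iberia: gene flow into the terminal Creole clusters between the present and t1 (backward lineage movement Creole -> Iberia).",
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
    {"from": ["Col", "TXL", "SNP"], "to": "Iber", "start": 0, "end": "t1", "rate": "m"}
  ]
}
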