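{
  "id": 7,
  "comment": "Scenario 2 (expansion) combined with scenario 4 (migration before t1).",
  "populations": ["Iber", "Col", "TXL", "SNP", "AMR"],
  "generation_length_years": 5,
  "sizes": {"Iber": "Ne_Iber", "Col": "Ne_Col", "TXL": "Ne_TXL", "SNP": "Ne_SNP", "AMR": "Ne_ANC"},
  "splits": [
    {"time": "t1", "derived": "Col", "ancestral": "AMR"},
    {"time": "t1", "derived": "SNP", "ancestral": "AMR"},
    {"time": "t2", "derived": "TXL", "ancestral": "AMR"},
    {"time": "t3", "derived": "AMR", "ancestral": "Iber"}
  ],
  "growth": [
    {"population": "AMR", "start": "t1", "end": "t2", "start_size": "Ne_1", "end_size": "Ne_2"},
    {"population": "AMR", "start": "t2", "end": "t3", "start_size": "Ne_2", "end_size": "Ne_ANC"}
  ],
  "migration": [
    {"from": ["AMR", "TXL"], "to": "Iber", "start": "t1", "end": "t3", "rate": "m"}
  ]
}
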