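{
  "id": 1,
  "comment": "Base colonization topology: American ancestor (AMR) founded from Iberia at t3 at the bottleneck size Ne_ANC; Texas Longhorn splits at t2; Colombian and Senepol clusters split at t1. Constant sizes, no migration.",
  "populations": ["Iber", "Col", "TXL", "SNP", "AMR"],
  "generation_length_years": 5,
  "sizes": {"Iber": "Ne_Iber", "Col": "Ne_Col", "TXL": "Ne_TXL", "SNP": "Ne_SNP", "AMR": "Ne_ANC"},
  "splits": [
    {"time": "t1", "derived": "Col", "ancestral": "AMR"},
    {"time": "t1", "derived": "SNP", "ancestral": "AMR"},
    {"time": "t2", "derived": "TXL", "ancestral": "AMR"},
    {"time": "t3", "derived": "AMR", "ancestral": "Iber"}
  ]
}
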