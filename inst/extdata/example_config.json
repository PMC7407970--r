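{
  "simulate": {
    "n_tumor": 200,
    "n_normal": 80,
    "n_mirna": 6,
    "n_mrna": 60,
    "planted_mmr_ids": ["mir-001", "mir-002"],
    "planted_edges": [
      {"mirna": "mir-001", "gene": "g0001", "sign": -1, "effect": 1.5},
      {"mirna": "mir-001", "gene": "g0002", "sign": -1, "effect": 1.5},
      {"mirna": "mir-001", "gene": "g0003", "sign": -1, "effect": 1.5},
      {"mirna": "mir-001", "gene": "g0004", "sign": -1, "effect": 1.5},
      {"mirna": "mir-001", "gene": "g0005", "sign": -1, "effect": 1.5},
      {"mirna": "mir-002", "gene": "g0011", "sign": -1, "effect": 1.5},
      {"mirna": "mir-002", "gene": "g0012", "sign": -1, "effect": 1.5},
      {"mirna": "mir-002", "gene": "g0013", "sign": -1, "effect": 1.5},
      {"mirna": "mir-002", "gene": "g0014", "sign": -1, "effect": 1.5},
      {"mirna": "mir-002", "gene": "g0015", "sign": -1, "effect": 1.5}
    ],
    "stage_trend": 1.0,
    "survival_beta": 0.8,
    "censor_rate": 0.4,
    "driver_roles": {
      "g0001": "tsg", "g0002": "tsg", "g0003": "tsg",
      "g0004": "tsg", "g0005": "tsg",
      "g0011": "oncogene", "g0012": "oncogene", "g0013": "oncogene",
      "g0014": "oncogene", "g0015": "oncogene"
    },
    "seed": 42
  },
  "n_boot": 20,
  "mi_null": 500,
  "nes_null": 500,
  "min_regulon": 3,
  "db": {"n_dbs": 2, "recall": 0.9, "precision": 0.5},
  "seed": 42
}
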