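{
  "version": "gail-model-2/1.0",
  "provenance": "Log relative-risk coefficients of the parsimonious Gail model (model 2) as published for the US breast cancer risk assessment tool; category codes: age_menarche ge14=0, 12to13=1, lt12=2; age_first_birth lt20=0, 20to24=1, 25to29=2, nulliparous=2, ge30=3; n_relatives 0=0, 1=1, ge2=2; n_biopsies 0=0, 1=1, ge2=2. Biopsy main effect interacts with age regime (>=50); first-birth effect interacts with family history.",
  "checksum_terms": 6,
  "log_rr": {
    "n_biopsies": 0.5292641,
    "age_menarche": 0.0940103,
    "age_first_birth": 0.2186262,
    "n_relatives": 0.9583027,
    "biopsies_x_age_ge50": -0.2880424,
    "first_birth_x_relatives": -0.1908113
  },
  "category_code": {
    "age_menarche": {"ge14": 0, "12to13": 1, "lt12": 2},
    "age_first_birth": {"lt20": 0, "20to24": 1, "25to29": 2,
                        "nulliparous": 2, "ge30": 3},
    "n_relatives": {"0": 0, "1": 1, "ge2": 2},
    "n_biopsies": {"0": 0, "1": 1, "ge2": 2}
  },
  "hyperplasia_multiplier": {"no": 0.93, "yes": 1.82, "unknown": 1.0}
}
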