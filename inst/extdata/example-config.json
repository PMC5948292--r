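{
  "seed": 1,
  "population": {
    "n_individuals": 20000,
    "n_base_years": 5,
    "zero_claim_prob": 0.30,
    "target_mean_claims": 221,
    "persistence_rho": 0.65
  },
  "simulation": {
    "horizon": 25,
    "schemes": ["community", "age_gender_28", "age_gender_quintile_140", "individual"],
    "opt_out_probs": [0.05, 0.10],
    "loading": 0.23,
    "operating_risk_premium": 100,
    "n_replicates": 5
  }
}
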