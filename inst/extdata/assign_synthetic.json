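{
  "name": "assign_synthetic",
  "description": "Synthetic fixture spec shaped like the ASSIGN score family (cigarettes-per-day dose, area deprivation as a plain quintile, family history, rheumatoid arthritis; no ethnicity). Coefficients are illustrative fixtures, not the published values.",
  "horizon": 10,
  "baseline_survival": {"male": 0.900, "female": 0.940},
  "applicability": {"age_min": 35, "age_max": 74, "sex": "both"},
  "missing_policy": {"sbp": 133, "chol_hdl_ratio": 4.2, "smoking": "never", "cigs_per_day": "none"},
  "terms": [
    {"covariate": "age_at_index", "transform": "identity", "coefficient": 0.070, "reference": 50},
    {"covariate": "sbp", "transform": "identity", "coefficient": 0.010, "reference": 133},
    {"covariate": "chol_hdl_ratio", "transform": "identity", "coefficient": 0.17, "reference": 4.2},
    {"covariate": "cigs_per_day", "transform": "categorical", "level": "1-10", "coefficient": 0.35},
    {"covariate": "cigs_per_day", "transform": "categorical", "level": "11-20", "coefficient": 0.50},
    {"covariate": "cigs_per_day", "transform": "categorical", "level": "21+", "coefficient": 0.75},
    {"covariate": "diabetes", "transform": "categorical", "level": "true", "coefficient": 0.55},
    {"covariate": "family_history_chd", "transform": "categorical", "level": "true", "coefficient": 0.30},
    {"covariate": "rheumatoid_arthritis", "transform": "categorical", "level": "true", "coefficient": 0.30},
    {"covariate": "deprivation_quintile", "transform": "identity", "coefficient": 0.08, "reference": 3}
  ]
}
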