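{
  "name": "framingham_synthetic",
  "description": "Synthetic fixture spec shaped like the Framingham 10-year CVD equation family (age, blood pressure, lipids, smoking, diabetes, LVH; no deprivation or ethnicity). Coefficients are illustrative fixtures, not the published values.",
  "horizon": 10,
  "baseline_survival": {"male": 0.895, "female": 0.945},
  "applicability": {"age_min": 35, "age_max": 74, "sex": "both"},
  "missing_policy": {"sbp": 132, "chol_hdl_ratio": 4.2, "smoking": "never"},
  "terms": [
    {"covariate": "age_at_index", "transform": "identity", "coefficient": 0.065, "reference": 50},
    {"covariate": "sbp", "transform": "identity", "coefficient": 0.011, "reference": 132},
    {"covariate": "chol_hdl_ratio", "transform": "identity", "coefficient": 0.18, "reference": 4.2},
    {"covariate": "smoking", "transform": "categorical", "level": "current", "coefficient": 0.55},
    {"covariate": "smoking", "transform": "categorical", "level": "past", "coefficient": 0.05},
    {"covariate": "diabetes", "transform": "categorical", "level": "true", "coefficient": 0.50},
    {"covariate": "lvh", "transform": "categorical", "level": "true", "coefficient": 0.50}
  ]
}
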