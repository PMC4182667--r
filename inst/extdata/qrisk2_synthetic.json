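{
  "name": "qrisk2_synthetic",
  "description": "Synthetic fixture spec shaped like the QRISK2 family (ethnicity, deprivation, comorbidities, an age-by-treated-hypertension interaction, sex-specific baseline survival). Persons with unrecorded ethnicity are scored as the reference level, and the score carries no calendar-year or consultation-frequency terms - the deliberate contrasts with the cohort's ground-truth model. Coefficients are illustrative fixtures, not any published or licensed release.",
  "horizon": 10,
  "baseline_survival": {"male": 0.915, "female": 0.942},
  "applicability": {"age_min": 35, "age_max": 74, "sex": "both"},
  "missing_policy": {"sbp": 130, "chol_hdl_ratio": 4.0, "bmi": 26, "smoking": "never"},
  "terms": [
    {"covariate": "age_at_index", "transform": "identity", "coefficient": 0.075, "reference": 55},
    {"covariate": "sbp", "transform": "identity", "coefficient": 0.012, "reference": 130},
    {"covariate": "chol_hdl_ratio", "transform": "identity", "coefficient": 0.15, "reference": 4},
    {"covariate": "bmi", "transform": "log", "coefficient": 0.55, "reference": 26},
    {"covariate": "smoking", "transform": "categorical", "level": "current", "coefficient": 0.65},
    {"covariate": "smoking", "transform": "categorical", "level": "past", "coefficient": 0.15},
    {"covariate": "ethnicity", "transform": "categorical", "level": "black", "coefficient": -0.05},
    {"covariate": "ethnicity", "transform": "categorical", "level": "indian", "coefficient": 0.30},
    {"covariate": "ethnicity", "transform": "categorical", "level": "other", "coefficient": 0.05},
    {"covariate": "treated_hypertension", "transform": "categorical", "level": "true", "coefficient": 0.35},
    {"covariate": "diabetes", "transform": "categorical", "level": "true", "coefficient": 0.65},
    {"covariate": "atrial_fibrillation", "transform": "categorical", "level": "true", "coefficient": 0.45},
    {"covariate": "chronic_renal_disease", "transform": "categorical", "level": "true", "coefficient": 0.35},
    {"covariate": "rheumatoid_arthritis", "transform": "categorical", "level": "true", "coefficient": 0.20},
    {"covariate": "family_history_chd", "transform": "categorical", "level": "true", "coefficient": 0.25},
    {"covariate": "deprivation_quintile", "transform": "identity", "coefficient": 0.06, "reference": 3},
    {"covariate": "age_at_index", "transform": "interaction", "coefficient": -0.005, "reference": 55, "with": "treated_hypertension", "with_level": true}
  ]
}
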