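{
  "description": "Row layout of the 49 x 32 model input matrix. Columns are update time steps (distinct observation times up to and including the prediction time); at most the 32 most recent steps are kept and shorter sequences are left-padded with all-zero columns.",
  "n_rows": 49,
  "n_steps": 32,
  "constant_rows": [
    "age",
    "male",
    "female",
    "antibiotics_before_prediction",
    "supplemental_o2_before_prediction",
    "heart_failure_history"
  ],
  "time_varying_features": [
    "sysbp", "diasbp", "hr", "temp", "resprate", "spo2",
    "creatinine", "bun", "bilirubin", "glucose", "inr", "wbc", "rbc",
    "platelets", "neutrophil_pct", "lymphocyte_pct", "monocyte_pct",
    "hematocrit", "lactate", "ast", "alt"
  ],
  "time_varying_encoding": "one (mask, value) row pair per feature, in list order, after the constant rows; mask is 1 when the feature was measured at that step, value is the z-scored measurement (0 when mask is 0)",
  "final_row": "time_delta: minutes since the previous kept step, z-scored with training-set statistics; 0 for the first kept step and for padded columns",
  "label_only_features": ["pao2", "fio2"],
  "notes": "age, male and female travel in observations.csv as admission-time rows; pao2 and fio2 feed the respiratory-failure criterion only and are not encoded"
}
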