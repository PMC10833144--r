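{
  "description": "Baseline characteristics of the biomarker-definition cohorts. Continuous variables carry mean/sd (normal) or median/q1/q3 (right-skewed); categorical variables carry count out of group n. Units: age years, eGFR ml/min/1.73m2 (CKD-EPI), proteinuria g/d, IFTA percent.",
  "groups": {
    "pFSGS": {
      "n": 19,
      "sex_male": {"count": 13},
      "age": {"mean": 46.3, "sd": 16.8},
      "eGFR": {"median": 56.0, "q1": 37.4, "q3": 94.9},
      "proteinuria": {"median": 8.03, "q1": 5.60, "q3": 11.11},
      "IFTA": {"mean": 12.4, "sd": 11.9},
      "nephrotic_range_proteinuria": {"count": 14}
    },
    "sFSGS": {
      "n": 44,
      "sex_male": {"count": 30},
      "age": {"mean": 57.6, "sd": 16.7},
      "eGFR": {"median": 31.1, "q1": 18.0, "q3": 43.9},
      "proteinuria": {"median": 2.56, "q1": 1.3, "q3": 4.00},
      "IFTA": {"mean": 28.3, "sd": 18.9},
      "nephrotic_range_proteinuria": {"count": 14}
    },
    "NC": {
      "n": 98,
      "sex_male": {"count": 73},
      "age": {"mean": 44.7, "sd": 15.4},
      "eGFR": {"median": 88.4, "q1": 72.6, "q3": 114.8},
      "proteinuria": {"median": 0.01, "q1": 0.01, "q3": 0.19},
      "IFTA": null,
      "nephrotic_range_proteinuria": {"count": 0}
    },
    "CKD_other": {
      "n": 100,
      "sex_male": {"count": 73},
      "age": {"mean": 45.5, "sd": 14.7},
      "eGFR": {"median": 40.7, "q1": 20.9, "q3": 76.8},
      "proteinuria": {"median": 2.00, "q1": 0.69, "q3": 5.80},
      "IFTA": {"mean": 16.6, "sd": 18.9},
      "nephrotic_range_proteinuria": {"count": 32}
    }
  }
}
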