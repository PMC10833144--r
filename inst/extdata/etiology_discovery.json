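{
  "description": "CKD etiologies (other than FSGS) of the age- and sex-matched discovery control cohort",
  "entries": [
    {"code": "AMYLOID", "label": "Amyloidosis", "n": 4},
    {"code": "ATN", "label": "Acute tubular necrosis", "n": 8},
    {"code": "C3MPPI_GP", "label": "Membranoproliferative GN, C3-GN, Postinfectious GN", "n": 3},
    {"code": "CAST", "label": "Myeloma cast nephropathy", "n": 2},
    {"code": "COLIVAD", "label": "Collagen IV associated diseases", "n": 6},
    {"code": "DNP", "label": "Diabetic nephropathy with nodular nephrosclerosis", "n": 10},
    {"code": "HINP", "label": "Hypertensive ischemic nephropathy", "n": 13},
    {"code": "IGANP", "label": "IgA nephropathy", "n": 16},
    {"code": "IGAPSH", "label": "Henoch-Schoenlein purpura (IgA vasculitis)", "n": 5},
    {"code": "INTN", "label": "Interstitial nephritis", "n": 6},
    {"code": "LN", "label": "Lupus nephritis", "n": 4},
    {"code": "MCGN", "label": "Minimal change glomerulopathy", "n": 5},
    {"code": "MEMGN", "label": "Membranous nephropathy", "n": 9},
    {"code": "VASCular", "label": "Thrombotic microangiopathy (cholesterol embolism)", "n": 2},
    {"code": "VASCulitis", "label": "Vasculitis", "n": 7}
  ]
}
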