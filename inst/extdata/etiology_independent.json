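{
  "description": "CKD etiologies (other than FSGS) of the independent specificity cohort",
  "entries": [
    {"code": "AMYLOID", "label": "Amyloidosis", "n": 1},
    {"code": "ATN", "label": "Acute tubular necrosis", "n": 1},
    {"code": "DNP", "label": "Diabetic nephropathy with nodular nephrosclerosis", "n": 66},
    {"code": "HINP", "label": "Hypertensive ischemic nephropathy", "n": 9},
    {"code": "IGANP", "label": "IgA nephropathy", "n": 63},
    {"code": "INTN", "label": "Interstitial nephritis", "n": 1},
    {"code": "LN", "label": "Lupus nephritis", "n": 3},
    {"code": "MCGN", "label": "Minimal change glomerulopathy", "n": 6},
    {"code": "MEMGN", "label": "Membranous nephropathy", "n": 6},
    {"code": "MPGN", "label": "Membranoproliferative glomerulonephritis", "n": 5},
    {"code": "VASCulitis", "label": "Vasculitis", "n": 9}
  ]
}
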