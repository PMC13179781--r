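{
  "converged": true,
  "loss": 1.05154093472489e-05,
  "cost_allocation": "per_tooth",
  "fitted": {
    "p_incidence_nat": 0.01,
    "SDF.p_incidence_tx": 0.00500015504630334,
    "SDF.p_extract_nocaries": 0.0769958898291,
    "SDF.p_arrest": 0.85,
    "SDF.p_extract_caries": 0.0500010393515867,
    "NAF.p_extract_nocaries": 0.399999999998476,
    "NAF.p_extract_caries": 0.113472821416297,
    "u_caries": 0.189051651327459
  },
  "achieved": [
    {
      "observable": "NAF.cost",
      "target": 8863,
      "achieved": 8862.80949282092,
      "rel_error": 2.14946608458796e-05,
      "within_tol": true
    },
    {
      "observable": "NAF.effect",
      "target": 1.39,
      "achieved": 1.39008126482602,
      "rel_error": 5.84639036143862e-05,
      "within_tol": true
    },
    {
      "observable": "SDF.cost",
      "target": 16660,
      "achieved": 16698.6586806317,
      "rel_error": 0.00232044901751135,
      "within_tol": true
    },
    {
      "observable": "SDF.effect",
      "target": 7.73,
      "achieved": 7.71249716047164,
      "rel_error": 0.00226427419513113,
      "within_tol": true
    }
  ],
  "note": "Synthetic calibrated parameters: transition probabilities and caries-state utilities fitted to published base-case outputs, not transcribed from the source study."
}
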