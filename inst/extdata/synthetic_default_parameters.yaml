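currency: 2025 US$
transition:
  p_init_caries: 0.68
  p_incidence_nat: 0.01
  SDF:
    p_incidence_tx: 0.005000155046303
    p_extract_nocaries: 0.0769958898291
    p_arrest: 0.85
    p_extract_caries: 0.050001039351587
  NAF:
    p_incidence_tx: 0.01
    p_extract_nocaries: 0.399999999998476
    p_arrest: 0.0
    p_extract_caries: 0.113472821416297
costs:
  c_sdf:
    base: 39.0
    low: 31.0
    high: 47.0
  c_naf:
    base: 33.0
    low: 27.0
    high: 39.0
  c_exam:
    base: 36.0
    low: 27.0
    high: 45.0
  c_xray:
    base: 45.0
    low: 37.0
    high: 53.0
  c_access:
    base: 129.0
    low: 93.0
    high: 165.0
utilities:
  NO_CARIES: 1.0
  ROOT_CARIES: 0.189051651327459
  ARREST: 1.0
  PERSISTENT: 0.189051651327459
  EXTRACTED: 0.0
settings:
  discount_rate: 0.03
  horizon_years: 19
  cycles_per_year: 2
  n_teeth: 21
  start_age: 45
  wtp: 50000.0
  cost_allocation: per_tooth
  cost_aggregation: cohort_sum
  effect_aggregation: per_tooth_mean
  cost_schedule: semiannual
psa:
  p_init_caries:
    family: beta
    mean: 0.68
    ci95:
    - 0.603455414012281
    - 0.751997973686751
  p_incidence_nat:
    family: beta
    mean: 0.01
    ci95:
    - 0.00072510106272
    - 0.03093483310314
  SDF.p_incidence_tx:
    family: beta
    mean: 0.005000155046303
    ci95:
    - 4.397276424206352e-05
    - 2.082257430468459e-02
  SDF.p_extract_nocaries:
    family: beta
    mean: 0.0769958898291
    ci95:
    - 0.040096724877307
    - 0.124528787614562
  SDF.p_arrest:
    family: beta
    mean: 0.85
    ci95:
    - 0.788840791612685
    - 0.902332800844083
  SDF.p_extract_caries:
    family: beta
    mean: 0.050001039351587
    ci95:
    - 0.02125715779142
    - 0.090015824342784
  NAF.p_incidence_tx:
    family: beta
    mean: 0.01
    ci95:
    - 0.00072510106272
    - 0.03093483310314
  NAF.p_extract_nocaries:
    family: beta
    mean: 0.399999999998476
    ci95:
    - 0.323243441616822
    - 0.47928298635309
  NAF.p_extract_caries:
    family: beta
    mean: 0.113472821416297
    ci95:
    - 0.06799703442038
    - 0.168685893285657
  c_sdf:
    family: gamma
    mean: 39.0
    ci95:
    - 31.411963918140049
    - 47.396621273561301
  c_naf:
    family: gamma
    mean: 33.0
    ci95:
    - 27.273330743141653
    - 39.264286093869522
  c_exam:
    family: gamma
    mean: 36.0
    ci95:
    - 27.566914021255091
    - 45.541303830834558
  c_xray:
    family: gamma
    mean: 45.0
    ci95:
    - 37.356221319121381
    - 53.344690929337595
  c_access:
    family: gamma
    mean: 129.0
    ci95:
    - 95.537210839047972
    - 167.409665890033267
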