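conditions:
  hypertension:
  - I10
  - I11
  - I12
  - I13
  - I14
  - I15
  diabetes:
  - E10
  - E11
  - E12
  - E13
  - E14
  - O24
  obesity: E66
  epilepsy: G40
  phenylketonuria: E70.0
  caesarean: O82
teratogen_codes:
- D07BB
- L04AX03
- retinoid
- thalidomide
- valproate
- warfarin
lookback_months: 3
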