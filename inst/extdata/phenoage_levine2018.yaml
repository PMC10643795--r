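# Phenotypic-age mapping: externally sourced constants transcribed from the
# published Levine et al. (2018) phenotypic-age model. Units declared below.
intercept: -19.9067
gamma: 0.0076927
horizon_months: 120
outer:
  a: 141.50225
  b: -0.00553
  c: 0.090165
weights:
  albumin: -0.0336
  creatinine: 0.0095
  glucose: 0.1953
  crp_ln: 0.0954
  lymphocyte_pct: -0.0120
  mcv: 0.0268
  rdw: 0.3306
  alp: 0.00188
  wbc: 0.0554
  age: 0.0804
units:
  albumin: g/L
  creatinine: umol/L
  glucose: mmol/L
  crp_ln: ln mg/dL
  lymphocyte_pct: '%'
  mcv: fL
  rdw: '%'
  alp: U/L
  wbc: 10^3 cells/uL
  age: years
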