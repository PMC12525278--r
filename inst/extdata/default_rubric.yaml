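schema: kda-rubric/1
criteria:
  acmg:
    type: map
    map:
      B: 1.0
      LB: 1.0
      VUS: 2.0
      LP: 3.0
      P: 3.0
    missing: 0.0
    range:
    - 0.0
    - 3.0
  cadd:
    type: breaks
    breaks:
    - 15.0
    - 30.0
    scores:
    - 0.0
    - 1.0
    - 2.0
    missing: 0.0
    range:
    - 0.0
    - 2.0
  frequency:
    type: freq_tiers
    rareMax: 5.0e-06
    commonMin: 0.001
    scores:
      rare: 3.0
      low: 2.0
      common: 1.0
    missing: 3.0
    range:
    - 1.0
    - 3.0
  mutationtaster:
    type: binary
    missing: 0.0
    range:
    - 0.0
    - 1.0
  polyphen2:
    type: binary
    missing: 0.0
    range:
    - 0.0
    - 1.0
  sift:
    type: binary
    missing: 0.0
    range:
    - 0.0
    - 1.0
  fathmm_mkl:
    type: binary
    missing: 0.0
    range:
    - 0.0
    - 1.0
  spliceai:
    type: binary
    missing: 0.0
    range:
    - 0.0
    - 1.0
  gerp:
    type: threshold_or_flag
    min: 2.0
    missing: 0.0
    range:
    - 0.0
    - 1.0
  constraint:
    type: constraint
    zMin: 3.09
    pliMin: 0.9
    missing: 0.0
    range:
    - 0.0
    - 1.0
  brain_expression:
    type: binary
    missing: 0.0
    range:
    - 0.0
    - 1.0
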