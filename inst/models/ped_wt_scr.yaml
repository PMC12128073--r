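name: ped_wt_scr
description: >
  Illustrative pediatric (cohort B) one-compartment model with allometric
  weight and a serum-creatinine power term on clearance. Parameter values are
  illustrative.
n_compartments: 1
parameters:
  CL:
    theta: 4.5
    terms:
    - kind: power
      covariate: weight
      ref: 70.0
      exp: 0.75
    - kind: power
      covariate: scr
      ref: 19.0
      exp: -0.25
  V1:
    theta: 40.0
    terms:
    - kind: power
      covariate: weight
      ref: 70.0
      exp: 1.0
omega:
  labels:
  - CL
  - V1
  matrix:
  - - 0.09
    - 0.0
  - - 0.0
    - 0.09
residual:
  type: combined
  sigma_add: 1.0
  sigma_prop: 0.2
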