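name: neo_wt_pma_scr_alt
description: >
  Second illustrative neonatal (cohort A) one-compartment model with the same
  covariate composition (weight, postmenstrual-age maturation and serum
  creatinine on clearance) but a different parameterisation, so that a
  neonatal candidate ensemble contains genuinely distinct models.
n_compartments: 1
parameters:
  CL:
    theta: 0.26
    terms:
    - kind: power
      covariate: weight
      ref: 2.5
      exp: 0.75
    - kind: hill_maturation
      covariate: pma
      tm50: 34.8
      gamma: 4.53
    - kind: power
      covariate: scr
      ref: 30.0
      exp: -0.34
  V1:
    theta: 1.6
    terms:
    - kind: power
      covariate: weight
      ref: 2.5
      exp: 1.0
omega:
  labels:
  - CL
  - V1
  matrix:
  - - 0.1024
    - 0.0
  - - 0.0
    - 0.09
residual:
  type: combined
  sigma_add: 0.8
  sigma_prop: 0.18
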