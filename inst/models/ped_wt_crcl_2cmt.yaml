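name: ped_wt_crcl_2cmt
description: >
  Illustrative pediatric (cohort B) two-compartment model: allometric weight
  on clearance and intercompartmental clearance, linear weight on both
  volumes, and a creatinine-clearance power term on clearance (creatinine
  clearance is derived from height, serum creatinine and postnatal age when
  not recorded). Parameter values are illustrative.
n_compartments: 2
parameters:
  CL:
    theta: 4.8
    terms:
    - kind: power
      covariate: weight
      ref: 70.0
      exp: 0.75
    - kind: power
      covariate: crcl
      ref: 120.0
      exp: 0.4
  V1:
    theta: 28.0
    terms:
    - kind: power
      covariate: weight
      ref: 70.0
      exp: 1.0
  Q:
    theta: 5.0
    terms:
    - kind: power
      covariate: weight
      ref: 70.0
      exp: 0.75
  V2:
    theta: 35.0
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
    - 0.1225
residual:
  type: combined
  sigma_add: 1.2
  sigma_prop: 0.2
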