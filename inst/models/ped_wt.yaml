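name: ped_wt
description: >
  Illustrative pediatric (cohort B) one-compartment model with body weight as
  the only covariate: allometric weight on clearance (exponent 0.75) and
  linear weight on volume. Parameter values are illustrative.
n_compartments: 1
parameters:
  CL:
    theta: 4.2
    terms:
    - kind: power
      covariate: weight
      ref: 70.0
      exp: 0.75
  V1:
    theta: 42.0
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
  - - 0.0625
    - 0.0
  - - 0.0
    - 0.09
residual:
  type: combined
  sigma_add: 1.0
  sigma_prop: 0.18
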