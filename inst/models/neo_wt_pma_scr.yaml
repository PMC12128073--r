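name: neo_wt_pma_scr
description: >
  Illustrative neonatal (cohort A) one-compartment model: clearance scales
  allometrically with weight, matures sigmoidally with postmenstrual age and
  decreases with serum creatinine; volume scales linearly with weight.
  Parameter values are illustrative, not a re-encoding of any published model.
n_compartments: 1
parameters:
  CL:
    theta: 0.23
    terms:
    - kind: power
      covariate: weight
      ref: 2.5
      exp: 0.75
    - kind: hill_maturation
      covariate: pma
      tm50: 33.3
      gamma: 3.68
    - kind: power
      covariate: scr
      ref: 29.0
      exp: -0.27
  V1:
    theta: 1.5
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
  - - 0.09
    - 0.0
  - - 0.0
    - 0.0625
residual:
  type: combined
  sigma_add: 1.0
  sigma_prop: 0.15
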