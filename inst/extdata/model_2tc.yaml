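frequencies:
- 0.03
- 0.025
- 0.02
- 0.028
- 0.022
- 0.018
- 0.014
- 0.011
states:
- label: S0
  multiplicity: 1.0
  energy: 0.0
  kappa:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  f_weight: 0.0
- label: 1nspi*
  multiplicity: 1.0
  energy: 3.41216105347298626
  kappa:
  - -0.11355186162944052
  - 0.10799775556597253
  - 0.0
  - 0.015
  - -0.012
  - 0.01
  - -0.008
  - 0.006
  f_weight: 0.10000000000000001
- label: 1pispi*
  multiplicity: 1.0
  energy: 3.65000001817973319
  kappa:
  - -0.14134303435963622
  - 0.11882035999850418
  - 0.0
  - -0.012
  - 0.015
  - -0.008
  - 0.01
  - -0.006
  f_weight: 1.0
- label: 3nspi*
  multiplicity: 3.0
  energy: 3.56441714562771805
  kappa:
  - -0.17559021525718596
  - 0.02428829951576301
  - 0.0
  - 0.01
  - -0.008
  - -0.012
  - 0.006
  - 0.015
  f_weight: 0.0
- label: 3pispi*
  multiplicity: 3.0
  energy: 3.12093742762593163
  kappa:
  - -0.10704478740708151
  - -0.05721693344976996
  - 0.0
  - -0.015
  - 0.01
  - 0.012
  - -0.006
  - -0.008
  f_weight: 0.0
couplings:
- state_i: 1nspi*
  state_j: 1pispi*
  mode: 3
  lambda: 0.04
- state_i: 3nspi*
  state_j: 3pispi*
  mode: 3
  lambda: 0.03
soc:
- singlet: 1nspi*
  triplet: 3pispi*
  magnitude_cm1: 160.0
- singlet: 1pispi*
  triplet: 3nspi*
  magnitude_cm1: 160.0
- singlet: 1nspi*
  triplet: 3nspi*
  magnitude_cm1: 50.0
- singlet: 1pispi*
  triplet: 3pispi*
  magnitude_cm1: 50.0
sublevel_pattern:
  re:
  - 0.70710678118654746
  - 0.0
  - 0.70710678118654746
  im:
  - 0.0
  - 0.0
  - 0.0
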