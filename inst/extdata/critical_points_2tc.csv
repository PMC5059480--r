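# Critical-point energies of 2-thiocytosine (MS-CASPT2), eV above the S0 minimum.
# bound: eq = calibration equality target, ge = lower bound.
label,kind,states,energy_ev,bound
FC 1pispi*,FC-point,1pispi*,3.65,eq
1pispi*/1nspi* CoIn,CoIn,1pispi*|1nspi*,3.02,eq
1pispi* min,minimum,1pispi*,3.02,eq
1nspi* min,minimum,1nspi*,2.95,eq
1nspi*/3pispi* MECP,MECP,1nspi*|3pispi*,3.05,eq
1pispi*/3nspi* MECP,MECP,1pispi*|3nspi*,3.08,eq
3nspi*/3pispi* CoIn,CoIn,3nspi*|3pispi*,3.03,eq
3nspi* min,minimum,3nspi*,3.02,eq
3pispi* min,minimum,3pispi*,2.85,eq
S0 relaxation barrier,barrier,1nspi*|S0,0.8,ge
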