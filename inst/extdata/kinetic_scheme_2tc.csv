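# First-order rate constants (fs^-1) of the three-step relaxation scheme
# S2 -> S1 -> {T2, T1}, T2 -> T1. S2 depopulation 1/160 fs^-1; total S1
# intersystem crossing 1/250 fs^-1 split 70/30 toward T2; T2 -> T1 internal
# conversion 1/480 fs^-1.
from,to,rate
S2,S1,0.00625
S1,T2,0.0028
S1,T1,0.0012
T2,T1,0.00208333333
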