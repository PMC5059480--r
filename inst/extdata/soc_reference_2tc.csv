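# Spin-orbit coupling magnitudes for 2-thiocytosine (cm^-1). The three values
# refer to different geometries/averages and are kept with distinct labels.
label,pair,magnitude_cm1
max near singlet-triplet MECPs,S1|T,170
trajectory average S1-T2,S1|T2,160
trajectory average S1-T1,S1|T1,50
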