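treatment_id,starch,reducing_sugar,vitamin_c
CK,16.61,0.430,19.28
C1T1,18.40,0.353,21.89
C2T1,19.08,0.325,22.55
C3T1,17.46,0.397,20.33
C1T2,19.12,0.317,23.06
C2T2,19.65,0.300,23.64
C3T2,17.90,0.370,21.29
C1T3,17.71,0.385,20.62
C2T3,17.03,0.400,20.07
C3T3,16.83,0.420,19.61
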