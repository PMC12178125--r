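treatment_id,starch,reducing_sugar,vitamin_c
CK,16.08,0.424,18.53
C1T1,18.32,0.337,21.62
C2T1,18.70,0.310,22.05
C3T1,17.27,0.378,19.75
C1T2,18.95,0.302,22.66
C2T2,19.37,0.286,22.98
C3T2,17.54,0.352,20.88
C1T3,17.71,0.363,20.13
C2T3,16.85,0.387,19.61
C3T3,16.47,0.408,19.25
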