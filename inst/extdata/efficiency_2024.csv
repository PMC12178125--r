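treatment_id,wue,pfp
CK,11.26,45.03
C1T1,12.74,50.53
C2T1,13.43,52.67
C3T1,12.34,47.77
C1T2,13.65,54.06
C2T2,15.14,58.85
C3T2,12.44,49.38
C1T3,12.26,48.72
C2T3,12.13,48.01
C3T3,11.82,46.99
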