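treatment_id,wue,pfp
CK,11.98,49.55
C1T1,13.14,54.24
C2T1,13.67,55.94
C3T1,12.52,51.67
C1T2,13.84,56.83
C2T2,15.11,61.41
C3T2,12.76,52.76
C1T3,12.74,52.63
C2T3,12.72,52.51
C3T3,12.19,50.28
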