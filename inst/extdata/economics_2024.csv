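treatment_id,water_fee,fertilizer_input,other_input,gross_income,net_income
CK,580,4535,12000,56192,39077
C1T1,580,4535,12000,63056,45941
C2T1,580,4535,12000,65728,48613
C3T1,580,4535,12000,59616,42501
C1T2,580,4535,12000,67472,50357
C2T2,580,4535,12000,73440,56325
C3T2,580,4535,12000,61632,44517
C1T3,580,4535,12000,60800,43685
C2T3,580,4535,12000,59920,42805
C3T3,580,4535,12000,58640,41525
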