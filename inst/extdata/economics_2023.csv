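treatment_id,water_fee,fertilizer_input,other_input,gross_income,net_income
CK,580,4535,12000,61840,44725
C1T1,580,22535,12000,67696,32581
C2T1,580,40535,12000,69808,16693
C3T1,580,58535,12000,64480,-6635
C1T2,580,22535,12000,70928,35813
C2T2,580,40535,12000,76640,23525
C3T2,580,58535,12000,65840,-5275
C1T3,580,22535,12000,65680,30565
C2T3,580,40535,12000,65536,12421
C3T3,580,58535,12000,62752,-8363
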