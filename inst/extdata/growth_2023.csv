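treatment_id,shoot_dm,tuber_dm,root_dm,plant_height,stem_diameter,lai,spad,yield
CK,5.17,10.12,0.138,75.65,16.10,3.12,43.50,38.65
C1T1,5.85,11.82,0.153,85.53,19.14,3.56,47.98,42.31
C2T1,6.62,13.26,0.155,94.67,19.95,3.95,53.90,43.63
C3T1,5.53,10.87,0.145,80.60,17.10,3.34,46.00,40.30
C1T2,6.76,13.60,0.157,99.92,20.65,4.05,58.90,44.33
C2T2,7.22,14.38,0.160,105.21,22.67,4.28,62.30,47.90
C3T2,5.76,11.35,0.151,83.21,17.63,3.52,46.95,41.15
C1T3,5.56,11.00,0.148,80.95,17.13,3.38,46.70,41.05
C2T3,5.48,10.51,0.144,78.73,16.89,3.30,45.53,40.96
C3T3,5.30,10.21,0.143,76.98,16.53,3.25,44.93,39.22
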