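treatment_id,shoot_dm,tuber_dm,root_dm,plant_height,stem_diameter,lai,spad,yield
CK,4.56,9.27,0.134,71.98,15.72,2.99,40.23,35.12
C1T1,5.22,11.06,0.152,83.27,18.88,3.47,45.43,39.41
C2T1,5.93,12.51,0.154,90.91,19.67,3.83,51.78,41.08
C3T1,4.94,9.93,0.144,77.09,16.91,3.22,43.26,37.26
C1T2,6.02,12.42,0.156,97.26,20.53,3.91,55.57,42.17
C2T2,6.51,13.74,0.158,102.77,22.39,4.18,58.35,45.90
C3T2,5.23,10.62,0.149,80.63,17.31,3.46,44.24,38.52
C1T3,4.97,10.15,0.146,77.45,17.00,3.30,43.85,38.00
C2T3,4.85,9.87,0.143,75.68,16.54,3.17,42.69,37.45
C3T3,4.75,9.75,0.142,74.34,16.36,3.14,41.85,36.65
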