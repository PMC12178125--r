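layer_top_cm,layer_bottom_cm,bulk_density,ph,organic_matter,total_n,avail_p,avail_k
0,20,1.39,8.0,26.5,2.22,17.50,119.5
20,40,1.41,7.9,10.12,0.62,6.93,78.32
40,60,1.42,8.1,7.38,0.48,3.58,63.28
60,80,1.45,8.0,3.58,0.37,2.81,48.51
80,100,1.40,7.9,2.23,0.25,2.69,39.25
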