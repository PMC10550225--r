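lat_min,lat_max,mean_dcm_m,sd_m
20,30,120,15
30,40,120,15
40,50,100,15
50,60,90,15
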