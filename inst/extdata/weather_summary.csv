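stat,temp_c,rh_pct,wind_ms,rain_mm
mean,22.74,37.18,2.78,1.34
median,21.96,31.30,1.80,0.00
max,32.33,92.30,9.97,42.81
min,8.77,14.70,0.00,0.00
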