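plot,scale,t_value,p_value,mae_pct,mre_pct,rmse_pct
Py1,FF,5.69,0.00,11.15,52.06,13.07
Py1,FX,3.71,0.00,11.53,52.97,15.25
Py2,FF,3.31,0.00,9.77,47.80,12.91
Py2,FX,2.14,0.03,10.20,48.65,15.13
Pa3,FF,12.23,0.00,15.83,64.18,16.94
Pa3,FX,9.79,0.00,15.89,64.53,17.74
Pa4,FF,12.53,0.00,14.95,62.20,15.96
Pa4,FX,9.88,0.00,14.82,61.89,16.62
Pa5,FF,8.73,0.00,16.79,63.46,18.53
Pa5,FX,7.62,0.00,16.74,63.12,19.07
Po6,FF,6.27,0.00,10.14,50.70,11.94
Po6,FX,4.45,0.00,10.15,50.54,13.54
Py-pa7,FF,6.69,0.00,12.23,55.56,14.25
Py-pa7,FX,5.65,0.00,12.09,54.75,14.91
Py-pa8,FF,3.98,0.00,9.86,49.94,13.10
Py-pa8,FX,2.78,0.01,10.19,50.65,14.80
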