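plot,b0,coef,predictor,mae_pct,mre_pct,rmse_pct
Py1,10.847,0.188,H_1,2.78,13.80,3.87
Py2,5.901,0.26,H_1,2.84,15.06,3.51
Pa3,34.117,-0.567,T_3,2.80,11.42,3.52
Pa4,38.742,-0.857,T_1,2.47,10.03,2.98
Pa5,43.341,-1.1047,T_2,3.50,14.23,4.29
Po6,8.491,0.226,H_1,2.39,12.01,3.30
Py-pa7,12.245,0.184,H_1,2.59,12.37,3.21
Py-pa8,9.593,0.619,H_1,4.39,23.57,5.43
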