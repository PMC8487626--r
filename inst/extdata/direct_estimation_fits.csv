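plot,alpha,beta,lambda,tau_h,mae_pct,mre_pct,rmse_pct
Py1,28.57,-4.83,0.41,13.54,2.79,13.81,3.57
Py2,37.70,-10.99,0.50,17.06,2.46,13.01,3.17
Pa3,23.19,0.56,0.36,11.78,3.04,12.68,3.81
Pa4,30.00,-3.56,0.35,11.55,3.64,12.04,3.59
Pa5,6.72,9.94,0.65,27.45,3.50,14.23,4.29
Po6,38.42,-10.70,0.32,10.42,2.72,13.65,3.64
Py-pa7,23.46,-1.64,0.53,18.66,2.26,10.69,2.85
Py-pa8,33.58,-8.61,0.42,13.76,2.16,11.54,2.82
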