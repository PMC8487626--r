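plot,scale,alpha,beta,r2,mae_pct,mre_pct,rmse_pct
Py1,FF,10.88,0.27,0.35,2.81,13.84,3.61
Py1,FX,11.15,0.25,0.38,2.86,14.58,3.64
Py2,FF,7.21,0.39,0.70,2.82,13.71,3.57
Py2,FX,7.40,0.37,0.70,2.76,13.47,3.57
Pa3,FF,12.12,0.25,0.27,4.19,15.87,5.28
Pa3,FX,12.34,0.24,0.27,4.23,16.02,5.32
Pa4,FF,11.68,0.27,0.36,3.43,13.20,4.52
Pa4,FX,11.89,0.26,0.36,3.41,13.19,4.53
Pa5,FF,12.55,0.26,0.28,5.09,18.61,6.09
Pa5,FX,12.76,0.25,0.27,5.08,18.60,6.12
Po6,FF,8.27,0.35,0.64,2.56,12.22,3.62
Po6,FX,8.45,0.34,0.65,2.53,12.15,3.61
Py-pa7,FF,10.51,0.28,0.51,2.79,12.33,3.56
Py-pa7,FX,10.66,0.27,0.52,2.76,12.21,3.53
Py-pa8,FF,8.09,0.35,0.62,2.50,12.56,3.47
Py-pa8,FX,8.28,0.33,0.62,2.46,12.36,3.45
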