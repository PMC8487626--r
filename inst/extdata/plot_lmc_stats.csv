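plot,n_days,mean,minimum,maximum,p25,p75,sd
Py1,82,20.75187,12.83160,34.00336,16.94826,23.18630,4.657846
Py2,85,19.47853,11.40590,34.26783,15.76367,21.31457,5.354328
Pa3,67,24.62457,17.79000,33.97879,21.28038,26.63266,4.055139
Pa4,74,24.18342,17.30228,32.53193,20.86533,27.07264,4.073415
Pa5,73,25.80851,15.64700,34.92262,20.62256,30.32734,5.590288
Po6,81,19.94026,12.70799,34.68168,16.65793,22.74278,4.672823
Py-pa7,79,21.43997,14.81812,33.54526,18.45807,23.69726,4.181648
Py-pa8,84,19.09674,11.96713,31.30165,16.13363,21.50934,4.216814
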