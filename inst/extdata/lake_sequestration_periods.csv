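lake,p_mean_a,p_sd_a,p_mean_b,p_sd_b,p_delta_pct,n_mean_a,n_sd_a,n_mean_b,n_sd_b,n_delta_pct
Latnjajaure,0.88,0.09,1.17,0.06,33,11.24,0.86,14.17,0.58,26
Abiskojaure,0.74,0.06,0.96,0.02,30,9.80,0.63,12.05,0.20,23
Batkajaure,1.16,0.05,1.30,0.04,12,14.13,0.55,15.51,0.35,10
Njalakjaure,0.46,0.07,0.96,0.07,110,6.93,0.71,12.05,0.75,74
Louvvajaure,1.07,0.03,1.42,0.02,32,13.22,0.26,16.75,0.15,27
Stor-Tjultrasket,1.22,0.05,1.43,0.02,17,14.73,0.48,16.89,0.18,15
Dunnervattnet,1.37,0.03,1.61,0.02,18,16.23,0.32,18.68,0.20,15
Stor Bjorsjon,1.34,0.03,1.50,0.02,12,15.95,0.26,17.63,0.16,11
Ovre Fjatsjon,1.14,0.03,1.36,0.03,19,13.93,0.30,16.14,0.29,16
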