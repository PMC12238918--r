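lake,latitude,longitude,elevation_m,lake_km2,catchment_km2,mean_total_p_ugL,mean_din_ugL,mean_toc_mgL,water_surface_km2,tundra_km2
Latnjajaure,68.3506,18.4883,976,0.74,9.46,2.7,25,1.0,0.77,1.58
Abiskojaure,68.4453,18.6139,487,2.79,366.9,4.5,32,1.6,15.02,193.95
Batkajaure,66.9145,16.6113,631,0.63,4.76,2.5,14,2.6,0.75,3.27
Njalakjaure,66.8169,16.6221,849,0.33,4.28,3.1,19,1.5,0.36,0.25
Louvvajaure,66.3931,18.1695,456,0.82,4.16,3.6,18,3.5,0.80,0.34
Stor-Tjultrasket,65.9625,16.0554,532,5.25,277.4,4.8,43,2.3,14.99,129.67
Dunnervattnet,64.2835,14.6917,445,2.67,100.8,4.0,28,5.9,7.89,15.46
Stor Bjorsjon,63.6151,12.2426,561,0.33,20.54,4.0,22,4.8,0.88,7.76
Ovre Fjatsjon,62.2359,12.7684,743,0.91,43.19,8.3,41,4.4,2.23,27.91
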