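genotype,n_pupae,n_eclosed,eclosion_mean_hmin,eclosion_sd_hmin,eclosion_rate_pct
Chro_control,8,4,108.22,03.42,97
Rheb,9,7,107.34,00.47,81
TOR,8,2,106.45,02.28,80
Tsc1,4,2,108.00,02.07,80
Tsc2_1,3,0,,,60
Tsc2_2,10,10,106.51,00.37,100
Atg5,6,4,107.07,00.51,100
Atg9,7,3,106.20,01.15,100
Atg12,6,1,104.00,00.00,95
Atg18,4,3,105.00,00.30,100
yki,6,1,110.30,00.00,90
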