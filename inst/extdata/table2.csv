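sample,total_sugars_pct,ara_pct,xyl_pct,glc_pct,gal_pct,uronic_acids_pct,ash_pct,proteins_pct,acetyl_pct,klason_lignin_pct,thio_yield_umol_per_g_kl,s_g_ratio,ca_mg_per_g,fa_mg_per_g
M,66.3,2.8,20.6,38.1,1.0,3.4,3.58,3.48,4.74,18.50,777.5,1.04,17.24,6.19
Mc-,67.2,2.7,22.1,38.0,0.8,3.2,2.61,2.17,3.75,19.01,823.5,0.92,19.00,6.79
Mc+,68.2,2.5,22.4,39.0,0.8,3.2,2.10,2.20,5.05,19.56,999.0,1.00,20.41,6.79
Mm-,67.6,3.4,22.3,37.1,1.1,3.3,4.01,2.42,3.98,14.79,748.5,0.90,12.54,5.19
Mm+,65.7,2.6,20.1,38.4,0.9,3.2,2.42,4.41,4.25,16.58,828.5,1.08,15.87,6.03
Mf-,67.3,3.6,19.8,37.6,1.4,4.3,3.38,3.70,4.06,15.43,720.5,1.28,15.37,5.70
Mf+,64.7,2.9,17.9,37.9,1.1,4.3,1.85,4.56,4.84,14.52,918.5,1.42,20.28,6.49
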