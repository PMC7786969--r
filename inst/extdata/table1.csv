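sample,yield_pct,d50_um,span,ssp_m2_per_g
M,NA,171.3,2.9,0.97
Mc-,18.5,315.6,1.9,0.60
Mc+,24.5,309.5,2.0,0.59
Mm-,11.7,201.4,2.1,0.87
Mm+,10.3,159.1,2.4,0.79
Mf-,18.6,62.8,2.4,1.51
Mf+,16.5,58.0,2.0,1.80
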