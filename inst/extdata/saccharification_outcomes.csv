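sample,sugar_release_7h_pct,number_decrease_7h_pct,size_decrease_7h_pct,t_half_sugar_min,t_half_number_min,t_half_size_min,control_number_decrease_pct
M,36.5,27,NA,NA,NA,NA,19
Mc,22,12,8,10.4,49.2,64.8,NA
Mm-,34,34,9,NA,49,NA,4
Mm+,38,22,10,10.1,150,150,NA
Mf-,52,32,17,6,10,19,18
Mf+,55,36,20,6,7,NA,28
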