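sample,swelling_ml_per_g,wrc_g_per_g
M,7.5,8.25
Mc-,5.0,5.60
Mc+,5.0,5.55
Mm-,6.0,7.15
Mm+,6.0,6.90
Mf-,7.5,8.85
Mf+,9.0,8.00
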