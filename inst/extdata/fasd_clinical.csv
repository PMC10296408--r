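subject_id,Age,ADOS_TOT,ADOS_comp,AQ_tot,nv_IQ,VABS_tot
B1,4,16,7,53,96,63
B2,5,n.a.,n.a.,56,78,74
B3,6,14,5,38,98,80
B4,4,9,5,n.a.,125,96
B5,3,14,5,48,106,93
B6,6,12,7,58,108,81
B7,5,9,6,96,87,87
B8,6,11,6,106,117,85
B9,5,9,5,53,102,85
B10,4,15,5,47,98,n.a.
B11,3,8,4,33,119,102
B12,3,11,5,95,110,77
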