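subject,condition,a_kpa,b,delta_t_s,e_pct_printed
S1,C2-D1,316.92,16.21,0.02,4.33
S1,C2-D2,311.26,16.13,0.07,3.41
S1,C2-D3,232.07,16.37,0.04,3.86
S2,C2-D1,260.35,16.87,0.07,8.84
S2,C2-D2,283.98,16.13,0.05,8.98
S2,C2-D3,209.44,16.82,0.07,7.78
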