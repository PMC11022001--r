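subject,condition,luminal_volume_mm3,dv_exp_printed_mm3
S1,C1,12.98,
S1,C2-D1,13.10,0.12
S1,C2-D2,13.86,0.88
S1,C2-D3,13.57,0.59
S2,C1,9.81,
S2,C2-D1,10.64,0.83
S2,C2-D2,10.38,0.57
S2,C2-D3,10.84,1.03
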