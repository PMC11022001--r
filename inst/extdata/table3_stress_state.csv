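subject,condition,p_mean_kpa,dp_pct,sigma1_mean_kpa,dsigma1_pct
S1,C2-D1,14.2,3.17,88.2,2.55
S1,C2-D2,14.3,4.12,88.9,3.35
S1,C2-D3,14.5,5,92.5,4.45
S2,C2-D1,14.8,7.09,64,6.08
S2,C2-D2,15.1,9.38,64.4,8.07
S2,C2-D3,15.4,11.35,69.1,10.59
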