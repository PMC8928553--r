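analyte,response_factor
DP1,1.16
DP2,1.12
DP3,0.99
DP4,0.33
dFCBG,1.09
2CBG,1.01
4CBG,1.03
HICBG,0.65
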