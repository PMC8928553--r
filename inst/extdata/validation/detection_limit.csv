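analyte,level_pct,conc_ugml,snr
cabotegravir,0.025,0.125,74.8
DP1,0.025,0.125,50.0
DP2,0.025,0.125,57.7
DP3,0.025,0.125,115.0
DP4,0.025,0.125,12.5
dFCBG,0.025,0.125,96.8
2CBG,0.025,0.125,59.0
4CBG,0.025,0.125,60.4
HICBG,0.025,0.125,46.9
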