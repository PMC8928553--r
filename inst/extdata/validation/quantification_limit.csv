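analyte,level_pct,conc_ugml,snr,rsd_area_pct
cabotegravir,0.05,0.25,170.4,0.00
DP1,0.05,0.25,104.0,0.42
DP2,0.05,0.25,123.3,2.25
DP3,0.05,0.25,222.7,2.75
DP4,0.05,0.25,25.8,2.80
dFCBG,0.05,0.25,204.5,1.41
2CBG,0.05,0.25,133.8,2.29
4CBG,0.05,0.25,123.0,1.72
HICBG,0.05,0.25,88.9,5.61
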