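analyte,slope,intercept,pearson_r
cabotegravir,24927,-1307,0.999
DP1,28984,-558,1.000
DP2,27865,-63,1.000
DP3,24753,-300,1.000
DP4,8303,-58,1.000
dFCBG,27223,-487,1.000
2CBG,25057,-719,1.000
4CBG,25708,-863,1.000
HICBG,16291,-1090,0.998
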