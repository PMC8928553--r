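impurity,level,level_pct,added_ugml,found_ugml,recovery_pct,rsd_pct
DP1,1,0.05,0.2266,0.2094,92.42,1.13
DP1,2,0.15,0.6798,0.6264,92.15,0.61
DP1,3,0.18,0.8157,0.7635,93.60,1.07
DP2,1,0.05,0.2389,0.2384,99.81,1.34
DP2,2,0.15,0.7166,0.7185,100.27,0.50
DP2,3,0.18,0.8600,0.8697,101.14,0.95
DP3,1,0.05,0.2628,0.2909,110.71,2.47
DP3,2,0.15,0.7883,0.8878,112.63,0.28
DP3,3,0.18,0.9459,1.0653,112.62,0.30
DP4,1,0.05,0.3785,0.2966,78.37,0.88
DP4,2,0.15,0.9378,0.9932,105.91,0.69
DP4,3,0.18,1.1355,1.0348,91.13,1.45
dFCBG,1,0.05,0.2823,0.3133,110.99,1.04
dFCBG,2,0.15,0.8468,0.9144,107.99,0.29
dFCBG,3,0.18,1.0161,1.0948,107.75,0.87
2CBG,1,0.05,0.2758,0.2857,103.60,1.57
2CBG,2,0.15,0.8273,0.8824,106.67,0.56
2CBG,3,0.18,0.9927,1.2140,122.30,0.61
4CBG,1,0.05,0.3038,0.3392,111.67,4.31
4CBG,2,0.15,0.9113,1.0279,112.81,1.22
4CBG,3,0.18,1.0935,1.2431,113.68,1.74
HICBG,1,0.05,0.2598,0.2701,103.99,1.91
HICBG,2,0.15,0.7793,0.8263,106.03,0.56
HICBG,3,0.18,0.9351,0.9978,106.70,0.93
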