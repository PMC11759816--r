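variable,mean_source1,se_source1,mean_source2,se_source2
proportion_elemental,0.74,0.061,0.26,0.061
proportion_isotopic,0.92,0.035,0.08,0.035
Li,1.66,0.071,2.33,0.047
Na,8912,175,8926,105
Mg,44.59,3.523,42.64,1.191
Cr,3.41,0.185,2.98,0.084
Mn,1.5,0.093,1.98,0.087
Sr,5241,125,4469,124
Sn,0.44,0.019,0.34,0.013
Ba,6.01,0.262,4.08,0.205
d18O,3.51,0.050,4.15,0.013
d13C,-5.51,0.130,-2.00,0.052
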