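variable,mean_juvenile,sd_juvenile,mean_adult,sd_adult,t,df,p_label
Li,1.9,0.4,2.1,0.4,-3.21,25,<0.01
Na,9057.3,675.1,11026.6,928.8,-11.18,25,<0.001
Mg,42.6,15.5,43.9,13.8,-0.64,23,0.53
Cr,3.3,0.9,3.8,1.1,-3.86,23,<0.001
Mn,1.9,0.5,1.2,0.710,5.30,23,<0.001
Sr,4461.9,680.9,15683.1,4385.2,-21.32,23,<0.001
Sn,0.4,0.1,0.4,0.1,0.71,23,0.48
Ba,4.9,1.5,15.0,7.2,-8.74,23,<0.001
d18O,3.6,0.3,4.3,0.3,-7.50,28,<0.001
d13C,-5.3,1.1,-2.2,1.0,-10.49,28,<0.001
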