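population,morph,fruit_C_mean,fruit_C_sd,fruit_HP_mean,fruit_HP_sd,spf_C_mean,spf_C_sd,spf_HP_mean,spf_HP_sd,fitness_C_mean,fitness_C_sd,fitness_HP_mean,fitness_HP_sd,pl,ci_low,ci_high
BGTC1,L,7.1,3.6,15.4,6.6,75.8,20.9,107.2,19.3,569.1,412.0,1701.2,884.8,0.665,0.607,0.721
BGTC2,L,3.5,1.7,6.9,3.5,52.6,16.5,72.1,15.8,192.5,124.0,512.6,324.8,0.624,0.556,0.687
PNP1,L,9.3,4.3,11.7,5.3,94.8,17.8,110.8,17.5,905.9,480.9,1320.2,695.1,0.314,0.202,0.414
PNP2,L,8.2,3.7,10.3,4.2,101.2,19.2,115.1,19.0,857.6,472.5,1226.8,619.6,0.301,0.177,0.404
BGTC1,S,7.4,4.3,15.8,5.4,65.1,21.7,112.6,13.6,539.9,453.2,1793.3,691.2,0.699,0.638,0.748
BGTC2,S,2.7,1.5,5.7,2.9,42.2,16.7,63.3,15.4,121.1,103.8,367.3,243.2,0.670,0.593,0.733
PNP1,S,9.2,5.3,10.6,5.1,85.0,17.9,110.1,21.0,821.0,553.2,1198.6,693.3,0.315,0.189,0.434
PNP2,S,8.9,4.7,11.1,4.3,99.6,15.8,106.8,19.3,918.0,574.7,1241.7,642.9,0.261,0.135,0.366
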