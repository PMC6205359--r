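population,morph,treatment,n,trait,mean,sd
BGTC1,L,C,100,flowering_onset,154.3,1.3
BGTC1,L,HP,97,flowering_onset,154.3,1.6
BGTC1,S,C,100,flowering_onset,154.2,1.6
BGTC1,S,HP,97,flowering_onset,154.1,1.3
BGTC2,L,C,98,flowering_onset,154.7,1.9
BGTC2,L,HP,90,flowering_onset,157.5,5.0
BGTC2,S,C,91,flowering_onset,154.0,2.0
BGTC2,S,HP,91,flowering_onset,155.1,2.4
PNP1,L,C,88,flowering_onset,158.4,1.8
PNP1,L,HP,93,flowering_onset,159.2,1.6
PNP1,S,C,96,flowering_onset,160.2,1.5
PNP1,S,HP,94,flowering_onset,157.8,1.9
PNP2,L,C,78,flowering_onset,161.2,1.1
PNP2,L,HP,95,flowering_onset,160.6,1.3
PNP2,S,C,88,flowering_onset,161.1,1.3
PNP2,S,HP,89,flowering_onset,162.4,2.6
BGTC1,L,C,100,plant_height,44.6,7.3
BGTC1,L,HP,97,plant_height,49.2,7.9
BGTC1,S,C,100,plant_height,45.6,7.7
BGTC1,S,HP,97,plant_height,44.3,5.9
BGTC2,L,C,98,plant_height,28.6,5.4
BGTC2,L,HP,90,plant_height,30.5,5.1
BGTC2,S,C,91,plant_height,29.0,4.9
BGTC2,S,HP,91,plant_height,29.6,5.6
PNP1,L,C,88,plant_height,34.6,5.8
PNP1,L,HP,93,plant_height,34.3,7.2
PNP1,S,C,96,plant_height,33.7,7.0
PNP1,S,HP,94,plant_height,35.6,6.3
PNP2,L,C,78,plant_height,28.0,5.5
PNP2,L,HP,95,plant_height,27.0,6.1
PNP2,S,C,88,plant_height,26.7,6.5
PNP2,S,HP,89,plant_height,27.5,7.9
BGTC1,L,C,100,n_flowers,18.7,6.3
BGTC1,L,HP,97,n_flowers,19.3,7.3
BGTC1,S,C,100,n_flowers,18.5,5.4
BGTC1,S,HP,97,n_flowers,20.5,6.1
BGTC2,L,C,98,n_flowers,8.5,2.5
BGTC2,L,HP,90,n_flowers,9.7,4.0
BGTC2,S,C,91,n_flowers,9.2,3.4
BGTC2,S,HP,91,n_flowers,8.4,3.0
PNP1,L,C,88,n_flowers,14.8,5.5
PNP1,L,HP,93,n_flowers,15.3,4.2
PNP1,S,C,96,n_flowers,15.3,7.1
PNP1,S,HP,94,n_flowers,14.7,4.7
PNP2,L,C,78,n_flowers,13.9,5.3
PNP2,L,HP,95,n_flowers,13.7,4.8
PNP2,S,C,88,n_flowers,15.4,6.0
PNP2,S,HP,89,n_flowers,14.1,5.1
BGTC1,L,C,100,corolla_tube_length,9.27,0.64
BGTC1,L,HP,97,corolla_tube_length,9.55,0.57
BGTC1,S,C,100,corolla_tube_length,10.23,0.65
BGTC1,S,HP,97,corolla_tube_length,10.03,0.62
BGTC2,L,C,98,corolla_tube_length,8.53,1.07
BGTC2,L,HP,90,corolla_tube_length,8.40,0.93
BGTC2,S,C,91,corolla_tube_length,9.36,0.69
BGTC2,S,HP,91,corolla_tube_length,8.94,0.61
PNP1,L,C,88,corolla_tube_length,10.04,0.77
PNP1,L,HP,93,corolla_tube_length,10.16,0.60
PNP1,S,C,96,corolla_tube_length,10.18,0.59
PNP1,S,HP,94,corolla_tube_length,10.02,0.69
PNP2,L,C,78,corolla_tube_length,9.92,0.58
PNP2,L,HP,95,corolla_tube_length,9.75,0.70
PNP2,S,C,88,corolla_tube_length,10.14,3.15
PNP2,S,HP,89,corolla_tube_length,9.94,0.58
BGTC1,L,C,100,corolla_tube_width,3.69,0.23
BGTC1,L,HP,97,corolla_tube_width,3.67,0.30
BGTC1,S,C,100,corolla_tube_width,3.02,0.24
BGTC1,S,HP,97,corolla_tube_width,3.05,0.23
BGTC2,L,C,98,corolla_tube_width,3.81,0.42
BGTC2,L,HP,90,corolla_tube_width,3.98,0.43
BGTC2,S,C,91,corolla_tube_width,3.25,0.29
BGTC2,S,HP,91,corolla_tube_width,3.06,0.32
PNP1,L,C,88,corolla_tube_width,3.51,0.32
PNP1,L,HP,93,corolla_tube_width,3.44,0.33
PNP1,S,C,96,corolla_tube_width,2.82,0.25
PNP1,S,HP,94,corolla_tube_width,2.85,0.27
PNP2,L,C,78,corolla_tube_width,3.31,0.28
PNP2,L,HP,95,corolla_tube_width,3.24,0.28
PNP2,S,C,88,corolla_tube_width,2.88,0.30
PNP2,S,HP,89,corolla_tube_width,2.84,0.26
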