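term,column,level1_mean,level2_mean
A,1,41.7435,44.8924
B,2,43.7364,42.8995
C,3,43.9219,42.7140
D,4,42.1578,44.4781
E,5,43.8906,42.7453
F,6,46.9984,39.6375
G,7,43.7826,42.8533
H,8,42.6729,43.9630
I,9,41.3817,45.2542
J,10,42.9600,43.6759
K,11,43.5897,43.0462
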