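element,z,zv,mass
H,1,1,1.008
B,5,3,10.81
C,6,4,12.011
N,7,5,14.007
O,8,6,15.999
F,9,7,18.998
Na,11,1,22.990
Mg,12,2,24.305
Si,14,4,28.085
P,15,5,30.974
S,16,6,32.06
Cl,17,7,35.45
K,19,1,39.098
Ca,20,2,40.078
Se,34,6,78.971
Br,35,7,79.904
I,53,7,126.904
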