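# Bond dipole moments in Debye by element pair and bond order (1/2/3/ar).
# Compiled from standard bond-moment tables (Smyth, Dielectric Behavior and
# Structure, 1955; Minkin, Osipov & Zhdanov, Dipole Moments in Organic
# Chemistry, 1970). Homonuclear bonds carry zero moment by symmetry.
# Element pairs stored with a <= b alphabetically.
a,b,order,value
C,C,1,0.00
C,C,2,0.00
C,C,3,0.00
C,C,ar,0.00
C,N,1,0.22
C,N,2,1.40
C,N,3,3.60
C,N,ar,0.80
C,O,1,0.74
C,O,2,2.40
C,O,ar,1.10
C,S,1,0.90
C,S,2,2.00
C,S,ar,1.20
C,F,1,1.41
C,Cl,1,1.46
Br,C,1,1.38
C,I,1,1.19
C,P,1,0.80
B,C,1,0.70
C,Si,1,0.60
N,N,1,0.00
N,N,2,0.00
N,N,ar,0.00
N,O,1,0.30
N,O,2,2.00
N,O,ar,0.90
N,S,1,0.50
N,S,2,1.60
N,S,ar,0.80
N,P,1,0.60
O,O,1,0.00
O,P,1,1.20
O,P,2,2.70
O,S,1,0.70
O,S,2,2.93
S,S,1,0.00
F,N,1,0.60
F,S,1,0.80
Cl,N,1,0.70
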