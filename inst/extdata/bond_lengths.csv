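# Standard covalent bond lengths in Angstrom by element pair and bond order
# (1 single, 2 double, 3 triple, ar aromatic). Values compiled from the
# standard reference tables of covalent bond lengths (Allen et al., J. Chem.
# Soc. Perkin Trans. 2 1987; CRC Handbook of Chemistry and Physics).
# Element pairs stored with a <= b alphabetically.
a,b,order,value
C,C,1,1.54
C,C,2,1.34
C,C,3,1.20
C,C,ar,1.39
C,N,1,1.47
C,N,2,1.28
C,N,3,1.16
C,N,ar,1.34
C,O,1,1.43
C,O,2,1.21
C,O,ar,1.36
C,S,1,1.82
C,S,2,1.60
C,S,ar,1.72
C,F,1,1.35
C,Cl,1,1.77
Br,C,1,1.94
C,I,1,2.14
C,P,1,1.84
B,C,1,1.56
C,Si,1,1.85
N,N,1,1.45
N,N,2,1.25
N,N,ar,1.32
N,O,1,1.40
N,O,2,1.21
N,O,ar,1.28
N,S,1,1.71
N,S,2,1.54
N,S,ar,1.60
N,P,1,1.77
O,O,1,1.48
O,P,1,1.63
O,P,2,1.50
O,S,1,1.57
O,S,2,1.43
S,S,1,2.05
F,N,1,1.36
F,S,1,1.56
Cl,N,1,1.75
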