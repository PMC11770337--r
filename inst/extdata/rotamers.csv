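aa,chi1,chi2,chi3,chi4
A,,,,
C,-60,,,
C,60,,,
C,180,,,
D,-60,180,,
D,60,180,,
D,180,180,,
E,-60,180,,
E,60,180,,
E,180,180,,
F,-60,90,,
F,60,90,,
F,180,90,,
G,,,,
H,-60,90,,
H,60,90,,
H,180,90,,
I,-60,170,,
I,60,170,,
I,180,170,,
K,-60,180,180,180
K,60,180,180,180
K,180,180,180,180
L,-60,170,,
L,60,170,,
L,180,170,,
M,-60,180,75,
M,60,180,75,
M,180,180,75,
N,-60,-20,,
N,60,-20,,
N,180,-20,,
Q,-60,180,-20,
Q,60,180,-20,
Q,180,180,-20,
R,-60,180,180,180
R,60,180,180,180
R,180,180,180,180
S,-60,,,
S,60,,,
S,180,,,
T,-60,,,
T,60,,,
T,180,,,
V,-60,,,
V,60,,,
V,180,,,
W,-60,90,,
W,60,90,,
W,180,90,,
Y,-60,90,180,
Y,60,90,180,
Y,180,90,180,
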