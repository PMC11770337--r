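aa,atom,type,bond,angle,dihedral
A,CB,C_ALI,1.53,110.4,cb
C,CB,C_ALI,1.53,110.4,cb
C,SG,S_THI,1.81,114.0,chi1
D,CB,C_ALI,1.53,110.4,cb
D,CG,C_CRX,1.52,112.0,chi1
E,CB,C_ALI,1.53,110.4,cb
E,CG,C_ALI,1.52,112.0,chi1
E,CD,C_CRX,1.52,112.0,chi2
F,CB,C_ALI,1.53,110.4,cb
F,CG,C_ALI,1.50,114.0,chi1
F,CZ,C_RNG,2.40,140.0,chi2
H,CB,C_ALI,1.53,110.4,cb
H,CG,C_ALI,1.50,113.0,chi1
H,NE2,N_NEU,2.20,140.0,chi2
I,CB,C_ALI,1.53,110.4,cb
I,CG1,C_ALI,1.53,110.0,chi1
I,CD1,C_ALI,1.53,113.0,chi2
K,CB,C_ALI,1.53,110.4,cb
K,CG,C_ALI,1.53,111.0,chi1
K,CD,C_ALI,1.53,111.0,chi2
K,CE,C_ALI,1.53,111.0,chi3
K,NZ,N_POS,1.47,111.0,chi4
L,CB,C_ALI,1.53,110.4,cb
L,CG,C_ALI,1.53,116.0,chi1
L,CD1,C_ALI,1.53,110.0,chi2
M,CB,C_ALI,1.53,110.4,cb
M,CG,C_ALI,1.53,111.0,chi1
M,SD,S_THI,1.81,112.0,chi2
M,CE,C_ALI,1.79,100.0,chi3
N,CB,C_ALI,1.53,110.4,cb
N,CG,C_AMD,1.52,112.0,chi1
N,OD1,O_AMD,1.23,120.0,chi2
Q,CB,C_ALI,1.53,110.4,cb
Q,CG,C_ALI,1.52,112.0,chi1
Q,CD,C_AMD,1.52,112.0,chi2
Q,OE1,O_AMD,1.23,120.0,chi3
R,CB,C_ALI,1.53,110.4,cb
R,CG,C_ALI,1.53,111.0,chi1
R,CD,C_ALI,1.53,111.0,chi2
R,NE,N_NEU,1.46,111.0,chi3
R,CZ,C_GUA,1.33,124.0,chi4
S,CB,C_POL,1.53,110.4,cb
S,OG,O_HYD,1.42,110.0,chi1
T,CB,C_POL,1.53,110.4,cb
T,OG1,O_HYD,1.43,109.0,chi1
V,CB,C_ALI,1.53,110.4,cb
V,CG1,C_ALI,1.53,110.0,chi1
W,CB,C_ALI,1.53,110.4,cb
W,CG,C_ALI,1.50,114.0,chi1
W,CZ2,C_RNG,2.60,135.0,chi2
Y,CB,C_ALI,1.53,110.4,cb
Y,CG,C_ALI,1.50,114.0,chi1
Y,CZ,C_RNGP,2.40,140.0,chi2
Y,OH,O_HYD,1.40,160.0,chi3
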