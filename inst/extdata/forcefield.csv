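atom_type,charge,eps,rmin_half,gb_radius
N_BB,-0.42,0.170,1.824,1.55
CA_BB,0.20,0.109,1.908,1.70
C_BB,0.60,0.086,1.908,1.70
O_BB,-0.38,0.210,1.661,1.50
C_ALI,0.00,0.109,1.908,1.70
C_POL,0.40,0.109,1.908,1.70
O_HYD,-0.40,0.210,1.721,1.52
S_THI,0.00,0.250,2.000,1.80
C_AMD,0.55,0.086,1.908,1.70
O_AMD,-0.55,0.210,1.661,1.50
C_CRX,-1.00,0.086,1.908,1.70
N_POS,1.00,0.170,1.824,1.55
C_GUA,1.00,0.086,1.908,1.70
N_NEU,0.00,0.170,1.824,1.55
C_RNG,0.00,0.120,2.400,2.20
C_RNGP,0.40,0.120,2.400,2.20
C_PE,0.00,0.118,1.960,1.70
CG_SPHERE,0.00,0.000,0.000,3.00
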