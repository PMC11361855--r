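monomer_id,n_methyl,stereo,side_smiles
Gly,0,none,
Ala,0,L,C
Val,0,L,C(C)C
Leu,0,L,CC(C)C
Ile,0,L,C(C)CC
Phe,0,L,Cc2ccccc2
Ser,0,L,CO
Thr,0,L,C(C)O
Met,0,L,CCSC
Trp,0,L,Cc2c[nH]c3ccccc23
Tyr,0,L,Cc2ccc(O)cc2
Asn,0,L,CC(N)=O
Gln,0,L,CCC(N)=O
Asp,0,L,CC(O)=O
Sar,1,none,
MeAla,1,L,C
MeVal,1,L,C(C)C
MeLeu,1,L,CC(C)C
MeIle,1,L,C(C)CC
MePhe,1,L,Cc2ccccc2
MeThr,1,L,C(C)O
dAla,0,D,C
dVal,0,D,C(C)C
dLeu,0,D,CC(C)C
dPhe,0,D,Cc2ccccc2
dTrp,0,D,Cc2c[nH]c3ccccc23
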