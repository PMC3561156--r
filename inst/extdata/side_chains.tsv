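name	smiles
methyl	*C
ethyl	*CC
propyl	*CCC
isopropyl	*C(C)C
hydroxy	*O
methoxy	*OC
ethoxy	*OCC
amino	*N
methylamino	*NC
dimethylamino	*N(C)C
fluoro	*F
chloro	*Cl
bromo	*Br
acetyl	*C(=O)C
methylester	*C(=O)OC
nitrile	*C#N
hydroxymethyl	*CO
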