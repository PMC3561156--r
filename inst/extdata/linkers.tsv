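name	smiles
direct
methylene	*C*
ethylene	*CC*
propylene	*CCC*
ether	*O*
oxymethylene	*OC*
vinylene	*C=C*
carbonyl	*C(=O)*
ester	*C(=O)O*
amide	*C(=O)N*
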