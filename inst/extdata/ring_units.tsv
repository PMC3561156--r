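name	smiles	class
benzene	*c1ccc(*)cc1	simple
pyridine	*c1ccc(*)cn1	simple
pyridazine	*c1ccc(*)nn1	simple
pyrimidine	*c1cnc(*)nc1	simple
pyrazine	*c1cnc(*)cn1	simple
pyrrole	*c1cc(*)c[nH]1	simple
furan	*c1cc(*)co1	simple
thiophene	*c1cc(*)cs1	simple
imidazole	*c1nc(*)c[nH]1	simple
pyrazole	*c1cc(*)[nH]n1	simple
oxazole	*c1ncc(*)o1	simple
thiazole	*c1ncc(*)s1	simple
triazole	*c1nc(*)[nH]n1	simple
cyclopropane	*C1CC1*	simple
cyclobutane	*C1CC(*)C1	simple
cyclopentane	*C1CCC(*)C1	simple
cyclohexane	*C1CCC(*)CC1	simple
cycloheptane	*C1CCCC(*)CC1	simple
tetrahydrofuran	*C1CCC(*)O1	simple
tetrahydropyran	*C1CCC(*)OC1	simple
pyrrolidine	*C1CCC(*)N1	simple
piperidine	*C1CCC(*)CN1	simple
piperazine	*C1CNCC(*)N1	simple
morpholine	*C1CNCC(*)O1	simple
naphthalene	*c1ccc2cc(*)ccc2c1	fused
quinoline	*c1ccc2nc(*)ccc2c1	fused
isoquinoline	*c1ccc2cnc(*)cc2c1	fused
quinoxaline	*c1cnc2cc(*)ccc2n1	fused
indole	*c1ccc2c(c1)cc(*)[nH]2	fused
benzofuran	*c1ccc2c(c1)cc(*)o2	fused
benzothiophene	*c1ccc2c(c1)cc(*)s2	fused
benzimidazole	*c1ccc2c(c1)nc(*)[nH]2	fused
indane	*C1Cc2ccccc2C1*	fused
tetralin	*C1CCc2ccccc2C1*	fused
decalin	*C1CCC2CCC(*)CC2C1	fused
coumarin	O=c1ccc2cc(*)ccc2o1	fused
chromone	O=c1ccoc2cc(*)ccc12	fused
purine	*c1nc2c([nH]cn2)cn1	fused
carbazole	*c1ccc2c(c1)[nH]c1ccccc12	fused
norbornane	*C1CC2CCC1C2*	bridged
bicyclooctane	*C1CC2CCC1CC2*	bridged
adamantane	*C1C2CC3CC1CC(C2)C3	bridged
spiro44nonane	*C1CCC2(CCC(*)C2)C1	spiro
spiro55undecane	*C1CCC2(CC1)CCCCC2	spiro
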