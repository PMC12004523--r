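"name","smarts"
"quinone_para","O=C1C=CC(=O)C=C1"
"quinone_ortho","O=C1C=CC=CC1=O"
"catechol","[OX2H]c1ccccc1[OX2H]"
"pyrogallol","[OX2H]c1cccc([OX2H])c1[OX2H]"
"hydroxyphenyl_hydrazone","[OX2H]c1ccc(cc1)[CX3]=[NX2][NX3]"
"acyl_hydrazone","[CX3]=[NX2][NX3H1][CX3]=[OX1]"
"ene_rhodanine","[SX1]=[CX3]1[SX2][CX3](=[CX3])[CX3](=[OX1])[NX3]1"
"rhodanine_core","[SX1]=[CX3]1[SX2][CX4][CX3](=[OX1])[NX3]1"
"alkylidene_barbiturate","[OX1]=C1[NX3][CX3](=[OX1])[NX3][CX3](=[OX1])C1=[CX3]"
"isothiazolone","[OX1]=[CX3]1[CX3]=[CX3][SX2][NX3]1"
"aromatic_azo","c[NX2]=[NX2]c"
"mannich_phenol","[OX2H]c1ccccc1[CX4H2][NX3]"
"thiourea","[NX3][CX3](=[SX1])[NX3]"
"cross_conjugated_dienone","[CX3]=[CX3][CX3](=[OX1])[CX3]=[CX3]"
"aminothiophene","[NX3H2]c1sccc1"
"beta_aminoketone_vinylogous","[NX3][CX3]=[CX3][CX3]=[OX1]"
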