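# Default substructure target list (24 targets: 12 single SMARTS patterns,
# 12 conjunctions). Each entry: target name -> list of SMARTS that must all
# match. Editable; see also default_substructure_targets().
carboxyl: [C(=O)O]
peroxide: [OO]
isopropyl: [CC(C)C]
benzylic: [cCc]
alkene: [C=C]
carbonyl: [C=O]
nitrile: ["C#N"]
benzene: [c1ccccc1]
sulfide: [S]
amine: [N]
ether: [COC]
tert_butyl: [CC(C)(C)C]
carboxyl_and_benzene: [C(=O)O, c1ccccc1]
carboxyl_and_isopropyl: [C(=O)O, CC(C)C]
isopropyl_and_benzylic: [CC(C)C, cCc]
peroxide_and_alkene: [OO, C=C]
carbonyl_and_amine: [C=O, N]
sulfide_and_benzene: [S, c1ccccc1]
ether_and_alkene: [COC, C=C]
carboxyl_and_peroxide: [C(=O)O, OO]
alkene_and_carbonyl: [C=C, C=O]
benzene_and_amine: [c1ccccc1, N]
tert_butyl_and_benzene: [CC(C)(C)C, c1ccccc1]
carboxyl_benzene_isopropyl: [C(=O)O, c1ccccc1, CC(C)C]
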