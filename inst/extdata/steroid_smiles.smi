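# curated structures for the packaged assay panels
# dialect: SMILES<whitespace>name; '#' lines are comments
# structures curated from canonical structure references and validated against
# molecular formulas; stereo descriptors present here are stripped on standardization
OCC(=O)[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3[C@@H](O)C[C@]12C cortisol
OCC(=O)[C@]1(O)CC[C@H]2[C@@H]3C[C@@H](C)C4=CC(=O)C=C[C@]4(C)[C@H]3[C@@H](O)C[C@]12C 6-methylprednisolone
OCC(=O)[C@]1(O)CC[C@H]2[C@@H]3CC[C@@H]4C[C@H](O)CC[C@]4(C)[C@H]3[C@@H](O)C[C@]12C allotetrahydrocortisol
OCC(=O)[C@]1(O)CC[C@H]2[C@@H]3C[C@H](O)C4=CC(=O)CC[C@]4(C)[C@H]3[C@@H](O)C[C@]12C 6beta-hydroxycortisol
OCC(=O)[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)C=C[C@]4(C)[C@H]3[C@@H](O)C[C@]12C prednisolone
CC(=O)[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3[C@@H](O)C[C@]12C 21-deoxycortisol
OCC(=O)[C@]1(O)CC[C@H]2[C@@]3(F)CCC4=CC(=O)CC[C@]4(C)[C@H]3[C@@H](O)C[C@]12C fludrocortisone
OCC(=O)[C@H]1CC[C@H]2[C@@H]3CC[C@H]4CC(=O)CC[C@]4(C)[C@H]3[C@@H](O)C[C@]12C 5beta-dihydrocorticosterone
OCC(=O)[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3[C@@H](O)C[C@]12C corticosterone
OCC(=O)[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C 11-deoxycortisol
CC12CCC(=O)C=C1C=C[C@@H]1[C@@H]2CC[C@]2(C)[C@H]1CC[C@@]21CCC(=O)O1 canrenone
CC(=O)[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C 17-hydroxyprogesterone
CC12CCC3C(C1CCC2=O)CCC1=C(O)C(=O)CC[C@]31C formestane
CC12CCC3C(C1CCC2=O)CCC1=CC(=O)CC[C@]31C androstenedione
OCC(=O)[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)C=C[C@]4(C)[C@H]3C(=O)C[C@]12C prednisone
OCC(=O)[C@]1(O)CC[C@H]2[C@@H]3CC[C@H]4C[C@H](O)CC[C@]4(C)[C@H]3C(=O)C[C@]12C tetrahydrocortisone
O=C1CC[C@]2(C)[C@H]1CC[C@H]1[C@@H]2CC=C2C[C@@H](OS(=O)(=O)O)CC[C@]12C dhea sulfate
CC(=O)[C@H]1CC[C@H]2[C@@H]3CC=C4C[C@@H](OS(=O)(=O)O)CC[C@]4(C)[C@H]3CC[C@]12C pregnenolone sulfate
CC(=O)[C@]1(O)CC[C@H]2[C@@H]3CC=C4C[C@@H](O)CC[C@]4(C)[C@H]3CC[C@]12C 17-hydroxypregnenolone
CC12CC[C@H]3[C@@H](CCc4cc(OS(=O)(=O)O)ccc34)[C@@H]1CCC2=O.C1CNCCN1 estropipate
C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc34)[C@@H]1CC[C@@H]2O estradiol
C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc34)[C@@H]1CCC2=O estrone
C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc34)[C@@H]1CC[C@]2(O)C#C ethinyl estradiol
C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc34)[C@@H]1C[C@H](O)[C@@H]2O estriol
CC(=O)[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C progesterone
CC(=O)[C@H]1CC[C@H]2[C@@H]3CC[C@H]4CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C 5beta-dihydroprogesterone
CC(=O)[C@H]1CC[C@H]2[C@@H]3CC[C@@H]4CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C 5alpha-pregnan-3,20-dione
CC(=O)[C@H]1CC[C@H]2[C@@H]3CC[C@H]4C[C@H](O)CC[C@]4(C)[C@H]3CC[C@]12C pregnanolone
CC(=O)[C@H]1CC[C@H]2[C@@H]3CC[C@@H]4C[C@H](O)CC[C@]4(C)[C@H]3CC[C@]12C allopregnanolone
CC(=O)[C@H]1CC[C@H]2[C@@H]3CC[C@@H]4C[C@@H](O)CC[C@]4(C)[C@H]3CC[C@]12C 5alpha-pregnan-3-ol-20-one
CC(=O)[C@H]1CC[C@H]2[C@@H]3CC[C@@H]4CC(O)CC[C@]4(C)[C@H]3CC[C@]12C 5alpha-pregnenolone
CC(=O)[C@]1(O)CC[C@H]2[C@@H]3C[C@@H](C)C4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C medroxyprogesterone
CC(=O)[C@H]1CC[C@H]2[C@@H]3CC=C4C[C@@H](O)CC[C@]4(C)[C@H]3CC[C@]12C pregnenolone
CC12CCC3C(C1CCC2=O)CC(=C)C1=CC(=O)C=C[C@]31C exemestane
O[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@H]4[C@H]3CC[C@]12C nandrolone
O[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C testosterone
C[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C methyltestosterone
O[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)C=C[C@]4(C)[C@H]3CC[C@]12C boldenone
O[C@H]1CC[C@H]2[C@@H]3CCC4=C(Cl)C(=O)CC[C@H]4[C@H]3CC[C@]12C 19-norclostebol
C#C[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@H]4[C@H]3CC[C@]12C norethindrone
O[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3[C@@H](O)C[C@]12C 11beta-hydroxytestosterone
C[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)C=C[C@]4(C)[C@H]3CC[C@]12C methandrostenolone
C[C@]1(O)CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@H]4[C@H]3CC[C@]12C normethandrolone
CCC(=O)O[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C testosterone propionate
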