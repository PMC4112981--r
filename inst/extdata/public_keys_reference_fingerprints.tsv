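# reference 166-key fingerprints computed with an independent public-keys
# implementation (RDKit MACCS) on the standardized packaged structures;
# used only as a cross-validation oracle in the test suite
# columns: name <TAB> hex bits (keys 1..166, MSB-first, zero-padded)
cortisol	0000004000004800411040e129993403b132edeb38
6-methylprednisolone	0000004000004800411040e129993403b13aedeb38
allotetrahydrocortisol	0000000000000800410040e109993403b032edeb38
6beta-hydroxycortisol	0000004000004800411040e129993403b132edeb38
prednisolone	0000004000004800411040e129993403b132edeb38
21-deoxycortisol	00000040000040004110006129913403b13aed4b38
fludrocortisone	0000004000404800411042e129b93403b532edeb38
5beta-dihydrocorticosterone	00000000000000004100402109993403b132edeb38
corticosterone	00000040000040004110402129993403b132edeb38
11-deoxycortisol	0000004000004800411040e129993403b132edeb38
canrenone	000000400000408040102001289134239182e94b38
17-hydroxyprogesterone	00000040000040004110006129913403912aed4b38
formestane	000000400000400041100061289134039122ed4b38
androstenedione	000000400000400040100001289134039102ad4338
prednisone	0000004000004800411040e129993403b132edeb38
tetrahydrocortisone	0000000000000800410040e109993403b132edeb38
dhea sulfate	0000004003014258689001212cd13417d132f94b38
pregnenolone sulfate	0000004003014258689001212cd13417d13afd4b38
17-hydroxypregnenolone	00000040000040004110006129913403b02aed4b38
estropipate	0000000003010258688001010cd1b417d133f54b78
estradiol	0000000000000000400000610991b403b023a50b78
estrone	0000000000000000400000210891b4039023a54b78
ethinyl estradiol	0000800000000000400000610991b403b023a50b78
estriol	0000000000000400410000610991b403b023e50b78
progesterone	00000040000040004010000128913403910aad4338
5beta-dihydroprogesterone	00000000000000004000000108913403910aad4338
5alpha-pregnan-3,20-dione	00000000000000004000000108913403910aad4338
pregnanolone	00000000000000004000006109913403902aad4b38
allopregnanolone	00000000000000004000006109913403902aad4b38
5alpha-pregnan-3-ol-20-one	00000000000000004000006109913403902aad4b38
5alpha-pregnenolone	00000000000000004000006109913403902aad4b38
medroxyprogesterone	00000040000040004110006129913403912aed4b38
pregnenolone	00000040000040004010004129913403902aad4b38
exemestane	000000404000400040100001289134039102ad4338
nandrolone	000000400000400040100061299134039022a54b38
testosterone	000000400000400040100061299134039022ad4b38
methyltestosterone	00000040000040004010006129913403902aad4b38
boldenone	000000400000400040100061299134039022ad4b38
19-norclostebol	0000004000004000401002612bb134039422a54b38
norethindrone	000080400000400040100061299134039022a54b38
11beta-hydroxytestosterone	00000040000040004010006129913403b022ed4b38
methandrostenolone	00000040000040004010006129913403902aad4b38
normethandrolone	000000400000400040100061299134039022ad4b38
testosterone propionate	00000040000040004010000128917427910aed6b38
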