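assay,compound,cross_reactivity_pct,provenance,likelihood_printed
cortisol,cortisol,100,measured,High (assay target)
cortisol,6-methylprednisolone,249,measured,High
cortisol,allotetrahydrocortisol,165,package insert,"Unknown, serum/plasma concentrations not reported"
cortisol,6beta-hydroxycortisol,158,package insert,"Unknown, serum/plasma concentrations not reported"
cortisol,prednisolone,148,measured,High
cortisol,21-deoxycortisol,45.4,package insert,"Low, except in patients with 21-hydroxylase deficiency"
cortisol,fludrocortisone,7.7,measured,Low
cortisol,5beta-dihydrocorticosterone,4.9,measured,"Unknown, serum/plasma concentrations not reported"
cortisol,corticosterone,4.6,measured,Low
cortisol,11-deoxycortisol,4.6,measured,"Low, except in patients following metyrapone challenge or who have 11beta-hydroxylase deficiency"
cortisol,canrenone,1.8,measured,"Low, except if cortisol measured during peak canrenone concentrations"
cortisol,17-hydroxyprogesterone,1.6,measured,"Low, except in patients with 21-hydroxylase deficiency"
cortisol,formestane,1.2,measured,Low
cortisol,androstenedione,0.9,measured,Low
cortisol,prednisone,0.3,measured,Low
dhea_sulfate,dhea sulfate,100,measured,High (assay target)
dhea_sulfate,pregnenolone sulfate,2.1,measured,"Low, possible minor effect around time of parturition"
dhea_sulfate,17-hydroxyprogesterone,0.08,measured,"Low, possible minor effect in 21-hydroxylase deficiency"
dhea_sulfate,17-hydroxypregnenolone,0.05,measured,Low
estradiol,estradiol,100,measured,High (assay target)
estradiol,estrone,0.54,measured,Low
estradiol,ethinyl estradiol,0.23,measured,Low
estradiol,estriol,0.09,measured,Possible contribution in pregnancy
progesterone,progesterone,100,measured,High (assay target)
progesterone,5beta-dihydroprogesterone,18.2,measured,Possible significant contribution for individuals with progesterone concentrations on the lower end of reference interval
progesterone,17-hydroxyprogesterone,1.2,measured,"Low, except in patients with 21-hydroxylase deficiency"
progesterone,pregnanolone,0.90,measured,Low
progesterone,allopregnanolone,0.82,measured,Low
progesterone,medroxyprogesterone,0.67,measured,Possible significant contribution for individuals with progesterone concentrations on the lower end of reference interval
progesterone,corticosterone,0.54,measured,Low
progesterone,11-deoxycortisol,0.39,measured,"Low, except in patients following metyrapone challenge or who have 11beta-hydroxylase deficiency"
progesterone,nandrolone,0.17,measured,Low
progesterone,pregnenolone,0.12,measured,Low
progesterone,exemestane,0.09,measured,Possible significant effect if progesterone measured near peak of exemestane plasma concentration
progesterone,androstenedione,0.09,measured,Low
testosterone,testosterone,100,measured,High (assay target)
testosterone,methyltestosterone,12.2,measured,"High, especially if measured during peak concentration"
testosterone,boldenone,7.2,measured,"Likely low, although there is lack of human pharmacokinetic data"
testosterone,19-norclostebol,6.7,measured,"Unknown, no human pharmacokinetic data available"
testosterone,norethindrone,6.7,measured,"Possible significant contribution in women taking norethindrone, especially if specimen drawn near peak of norethindrone concentration"
testosterone,11beta-hydroxytestosterone,5.5,measured,"Unknown, no human pharmacokinetic data available"
testosterone,methandrostenolone,5.4,measured,"Unknown, no human pharmacokinetic data available"
testosterone,normethandrolone,5.4,measured,"Unknown, no human pharmacokinetic data available"
testosterone,nandrolone,2.1,measured,Low
testosterone,androstenedione,1.2,measured,Low
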