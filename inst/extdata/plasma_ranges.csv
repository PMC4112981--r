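assay,compound,population,low_ng_ml,high_ng_ml,citation
cortisol,cortisol,morning,62,194,ref-19
cortisol,cortisol,afternoon,23,119,ref-19
cortisol,6-methylprednisolone,after oral or intravenous administration,NA,1000,ref-20
cortisol,prednisolone,pediatric transplant patients,NA,400,ref-21
cortisol,21-deoxycortisol,pediatric controls,0.28,0.43,ref-22
cortisol,21-deoxycortisol,patients with 21-hydroxylase deficiency,NA,140,ref-22
cortisol,fludrocortisone,after single dose,NA,0.36,ref-23
cortisol,corticosterone,18 years and younger,0.18,2.0,ref-24
cortisol,corticosterone,<18 years,0.53,1.6,ref-24
cortisol,11-deoxycortisol,pediatric controls,0.17,1.8,ref-22
cortisol,11-deoxycortisol,patients with 11beta-hydroxylase deficiency,NA,63,ref-22
cortisol,11-deoxycortisol,following metyrapone challenge,NA,250,ref-25
cortisol,canrenone,patients receiving spironolactone,10,1000,ref-26
cortisol,17-hydroxyprogesterone,pediatric controls,0.08,2.0,ref-22
cortisol,17-hydroxyprogesterone,21-hydroxylase deficiency,NA,1005,ref-22
cortisol,formestane,breast cancer patients,NA,14,ref-29
cortisol,androstenedione,before onset of puberty,NA,0.86,ref-30
cortisol,androstenedione,21-hydroxylase deficiency,NA,3.2,ref-30
cortisol,prednisone,pediatric transplant patients receiving prednisolone,NA,57,ref-21
dhea_sulfate,dhea sulfate,infants,NA,6070,ref-31
dhea_sulfate,dhea sulfate,females > 1 year old,5,4070,ref-31
dhea_sulfate,dhea sulfate,males > 1 year old,5,4920,ref-31
dhea_sulfate,pregnenolone sulfate,adult controls,21,84,ref-32
dhea_sulfate,pregnenolone sulfate,pregnancy,NA,1580,ref-33
dhea_sulfate,17-hydroxyprogesterone,pediatric controls,0.1,2.0,ref-22
dhea_sulfate,17-hydroxyprogesterone,21-hydroxylase deficiency,NA,1005,ref-22
dhea_sulfate,17-hydroxypregnenolone,healthy females,NA,4.3,ref-34
dhea_sulfate,17-hydroxypregnenolone,healthy males,NA,4.8,ref-34
dhea_sulfate,17-hydroxypregnenolone,premature infants,NA,100,ref-36
estradiol,estradiol,males,0.01,0.04,ref-37
estradiol,estradiol,premenopausal females,0.013,0.50,ref-37
estradiol,estradiol,pregnancy,NA,4.3,ref-37
estradiol,estrone,males,NA,0.06,ref-24
estradiol,estrone,females,NA,0.2,ref-24
estradiol,ethinyl estradiol,while on medication,NA,0.1,ref-38
estradiol,estriol,pregnancy,NA,18,ref-42
estradiol,estriol,non-pregnant females,NA,2.4,ref-43
progesterone,progesterone,males,0.2,1.4,ref-44
progesterone,progesterone,women,NA,27,ref-44
progesterone,5beta-dihydroprogesterone,adults,NA,0.8,ref-45
progesterone,17-hydroxyprogesterone,pediatric controls,0.08,2.0,ref-22
progesterone,17-hydroxyprogesterone,21-hydroxylase deficiency,NA,1005,ref-22
progesterone,pregnanolone,women,NA,17,ref-33
progesterone,allopregnanolone,women,NA,29,ref-33
progesterone,medroxyprogesterone,following dosing in women,NA,100,ref-46
progesterone,corticosterone,18 years and younger,0.18,2.0,ref-24
progesterone,corticosterone,<18 years,0.53,1.6,ref-24
progesterone,11-deoxycortisol,pediatric controls,0.17,1.8,ref-22
progesterone,11-deoxycortisol,11beta-hydroxylase deficiency,NA,63,ref-22
progesterone,11-deoxycortisol,metyrapone challenge,NA,250,ref-25
progesterone,nandrolone,men following intramuscular injection,NA,5.16,ref-47
progesterone,pregnenolone,women,NA,3.27,ref-33
progesterone,exemestane,post-menopausal women,NA,441,ref-48
progesterone,androstenedione,before onset of puberty,NA,0.86,ref-30
progesterone,androstenedione,21-hydroxylase deficiency,NA,3.2,ref-30
testosterone,testosterone,males,0,10,ref-49
testosterone,testosterone,females,0,0.5,ref-49
testosterone,methyltestosterone,following single dose,NA,40,ref-50
testosterone,boldenone,horses following dosing,NA,1.1,ref-51
testosterone,norethindrone,while on medication,NA,20,ref-39
testosterone,nandrolone,following intramuscular injection,NA,5.16,ref-47
testosterone,androstenedione,before onset of puberty,NA,0.86,ref-30
testosterone,androstenedione,21-hydroxylase deficiency,NA,3.2,ref-30
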