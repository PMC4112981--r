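assay,population,low_ng_ml,high_ng_ml
cortisol,adults (morning),62,194
cortisol,adults (afternoon),23,119
dhea_sulfate,infants,NA,6070
dhea_sulfate,females > 1 year old,5,4070
dhea_sulfate,males > 1 year old,5,4920
estradiol,males,0.01,0.04
estradiol,premenopausal females,0.013,0.50
estradiol,pregnancy,NA,4.3
progesterone,males,0.2,1.4
progesterone,women,NA,27
testosterone,males,0,10
testosterone,females,0,0.5
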