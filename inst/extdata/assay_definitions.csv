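assay,target_compound,spike_ng_ml,decision_level_ng_ml
cortisol,cortisol,1000,23
dhea_sulfate,dhea sulfate,50000,400
estradiol,estradiol,1000,0.04
progesterone,progesterone,1000,1.4
testosterone,testosterone,100,3
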