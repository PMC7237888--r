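system,proxy_variable,scale,normal,lethal_low,lethal_high,direction,observed_class
PTH,ionized calcium (mM),linear,1.2,0.9,2.5,up,mutant_expansion
insulin,blood glucose (mM),linear,5,3,14,down,autoimmune
glucagon,blood glucose (mM),linear,5,3,33,up,mutant_expansion
renin,systolic blood pressure (mmHg),linear,120,90,180,up,mutant_expansion
thyroxine,free T4 (ng/dl),linear,1.3,0.1,10.9,up,autoimmune
gastric acid,stomach pH,log10,1.4,1,7,down,autoimmune
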