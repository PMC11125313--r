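label,alpha,beta
Basic red 46,0.88,3.08
Methyl green,0.80,3.39
Sunset yellow,1.20,2.26
Yellow HE3G,0.40,6.78
Tartrazine,2.70,NA
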