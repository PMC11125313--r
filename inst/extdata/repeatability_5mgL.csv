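sample,measured_mg_per_L
M1,4.14
M2,4.51
M3,6.56
M4,4.44
M5,5.62
M6,5.01
M7,4.15
M8,5.36
M9,5.02
M10,4.89
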