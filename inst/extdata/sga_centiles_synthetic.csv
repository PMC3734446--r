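sex,gestation,p10_weight_g
M,33,1999
M,34,2118
M,35,2244
M,36,2378
M,37,2520
M,38,2671
M,39,2830
M,40,2999
M,41,3179
M,42,3368
M,43,3569
F,33,1863
F,34,1975
F,35,2093
F,36,2218
F,37,2350
F,38,2490
F,39,2639
F,40,2797
F,41,2964
F,42,3141
F,43,3328
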