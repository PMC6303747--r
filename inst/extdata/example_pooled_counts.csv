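interval_h,mating_order,n_females,eggs_m2,eggs_total
0,MP,13,417,828
0,PM,12,442,742
24,MP,15,373,542
24,PM,8,291,368
48,MP,7,143,203
48,PM,9,182,252
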