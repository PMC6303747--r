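interval_h,treatment,remated,total
0,M,13,57
0,P,13,56
24,M,15,44
24,P,10,43
48,M,8,29
48,P,10,33
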