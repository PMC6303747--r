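sterilization_order,interval_h,male_type,eggs_laid,eggs_hatched,eggs_brown
NR,0,normal,660,652,60
NR,0,sterile,637,43,0
NR,24,normal,516,505,46
NR,24,sterile,578,37,0
NR,48,normal,375,366,39
NR,48,sterile,427,38,0
RN,0,normal,660,652,60
RN,0,sterile,637,43,0
RN,24,normal,660,652,43
RN,24,sterile,562,28,0
RN,48,normal,660,652,29
RN,48,sterile,392,12,0
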