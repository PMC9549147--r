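age_from,age_to,annual_prob
45,50,0.0049
50,55,0.0076
55,60,0.0116
60,65,0.0177
65,70,0.0271
70,75,0.0415
75,80,0.0635
80,85,0.0972
85,90,0.1487
90,95,0.2276
95,100,0.3483
100,105,0.5330
105,120,0.8156
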