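date,p1,p2,p3,p4
2020-03-13,0.892,0.054,0.036,0.018
2020-04-27,0.247,0.378,0.295,0.080
2020-05-17,0.389,0.442,0.115,0.053
2020-08-14,0.823,0.084,0.009,0.084
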