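subject_id,arm,visit,days,total,item1,item2,item3,item4,item5,item6,item7,item8,item9,item10,item11,item12,item13,item14,item15,item16,item17
S0001,placebo,screening,8,33,2,4,3,2,1,2,2,4,0,2,4,1,2,1,1,2,0
S0001,placebo,baseline,8,29,0,4,3,2,1,2,2,4,0,2,2,1,2,1,2,1,0
S0002,placebo,screening,5,26,4,2,1,0,1,2,0,4,3,1,1,1,2,2,2,0,0
S0002,placebo,baseline,5,25,3,1,1,0,1,2,0,4,4,1,1,1,2,2,2,0,0
S0002,placebo,week2,5,18,,,,,,,,,,,,,,,,,
S0002,placebo,week4,5,16,,,,,,,,,,,,,,,,,
S0002,placebo,week8,5,15,,,,,,,,,,,,,,,,,
S0003,placebo,screening,6,31,1,1,4,2,0,1,1,2,3,2,4,2,2,2,0,2,2
S0003,placebo,baseline,6,29,1,2,3,2,0,1,2,2,3,2,4,2,2,2,0,1,0
S0003,placebo,week2,6,25,,,,,,,,,,,,,,,,,
S0003,placebo,week4,6,22,,,,,,,,,,,,,,,,,
S0003,placebo,week8,6,20,,,,,,,,,,,,,,,,,
S0004,active,screening,11,33,1,2,3,0,1,2,4,3,2,3,4,1,1,0,2,2,2
S0004,active,baseline,11,29,1,1,2,0,1,2,4,3,0,3,4,1,2,0,2,1,2
S0004,active,week2,11,21,,,,,,,,,,,,,,,,,
S0004,active,week4,11,16,,,,,,,,,,,,,,,,,
S0004,active,week8,11,8,,,,,,,,,,,,,,,,,
S0005,active,screening,7,22,2,2,0,1,2,1,1,2,2,0,1,1,2,1,2,1,1
S0005,active,baseline,7,21,3,2,0,1,2,1,1,2,2,0,1,1,2,0,0,2,1
S0005,active,week2,7,14,,,,,,,,,,,,,,,,,
S0005,active,week4,7,10,,,,,,,,,,,,,,,,,
S0005,active,week8,7,21,,,,,,,,,,,,,,,,,
S0006,active,screening,5,25,2,3,1,2,2,0,2,3,2,2,3,1,0,1,1,0,0
S0006,active,baseline,5,23,1,4,1,2,2,0,2,3,0,2,2,1,0,0,2,1,0
S0006,active,week2,5,10,,,,,,,,,,,,,,,,,
S0006,active,week4,5,11,,,,,,,,,,,,,,,,,
S0006,active,week8,5,2,,,,,,,,,,,,,,,,,
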