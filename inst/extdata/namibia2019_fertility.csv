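age_start,age_interval,asfr,units
15,5,66.9,per_1000
20,5,154.3,per_1000
25,5,160.0,per_1000
30,5,140.9,per_1000
35,5,103.9,per_1000
40,5,45.6,per_1000
45,5,11.2,per_1000
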