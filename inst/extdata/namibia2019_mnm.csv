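age_start,age_interval,cases,live_births,ratio,units
15,5,68,7939,8.57,per_1000
20,5,82,18050,4.57,per_1000
25,5,107,18241,5.86,per_1000
30,5,143,12772,11.19,per_1000
35,5,91,7492,12.19,per_1000
40,5,44,2895,15.06,per_1000
45,5,11,612,17.57,per_1000
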