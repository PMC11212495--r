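# radix: 100000
age_start,age_interval,lx,Lx
15,5,95283,474931.6
20,5,,470667.4
25,5,,464275.4
30,5,,455466.6
35,5,,443928.0
40,5,,429401.3
45,5,,411688.2
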