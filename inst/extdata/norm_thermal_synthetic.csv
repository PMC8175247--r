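x,value
18,6
19,7.14
20,8.16
21,9.06
22,9.84
23,10.5
24,11.04
25,11.46
26,11.76
27,11.94
28,12
29,11.94
30,11.76
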