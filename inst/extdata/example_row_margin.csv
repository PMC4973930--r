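value,prob
1,0.070000000000000007
2,0.13
3,0.14999999999999999
4,0.25
5,0.27000000000000002
6,0.070000000000000007
7,0.059999999999999998
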