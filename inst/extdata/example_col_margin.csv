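value,prob
1,0.16
2,0.17000000000000001
3,0.29999999999999999
4,0.25
5,0.12
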