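value,1,2,3,4,5
1,0.040000000000000001,0,0,0,0
2,0.080000000000000002,0.040000000000000001,0,0,0
3,0,0.12,0.080000000000000002,0,0
4,0,0,0.16,0,0.040000000000000001
5,0,0,0.040000000000000001,0.20000000000000001,0
6,0,0,0.040000000000000001,0.040000000000000001,0.040000000000000001
7,0,0,0.040000000000000001,0.040000000000000001,0
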