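value,occurrences
1,372
2,108
3,45
4,18
5,10
6,6
7,2
8,2
9,2
11,1
12,1
17,1
35,1
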