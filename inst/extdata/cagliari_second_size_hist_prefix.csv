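value,occurrences
1,338
2,50
3,17
4,15
5,9
6,10
7,10
8,5
9,5
10,6
11,3
12,3
764,1
810,1
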