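option,R,M,field,rof
1,25,10,20x20,1.22
2,22.5,10,20x20,1.17
3,20.8,10,20x20,1.13
4,18.7,10,20x20,1.08
5,16.7,10,20x20,1.02
6,14.8,10,20x20,0.97
7,13.1,10,20x20,0.89
8,11.4,10,20x20,0.82
9,9.9,8,20x20,0.83
10,8.5,6,20x20,0.87
11,7.2,6,20x20,0.79
12,6,4,20x20,0.86
13,32,10,10x10,1.35
14,29.5,10,10x10,1.32
15,27,10,10x10,1.29
16,24.5,10,10x10,1.26
17,22,10,10x10,1.21
18,20,10,10x10,1.12
19,17.7,10,10x10,1.06
20,15,10,10x10,1
21,13.2,10,10x10,0.94
22,11.1,10,10x10,0.94
23,9,8,10x10,0.95
24,6.9,6,10x10,0.96
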