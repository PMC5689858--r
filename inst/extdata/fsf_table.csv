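option,field,factor
1,circ3.5,0.687
1,5x5,0.985
1,10x10,1
1,circ14,1
1,20x20,1
1,circ25,1
6,circ3.5,0.868
6,5x5,1.006
6,10x10,1.004
6,circ14,1
6,20x20,1
6,circ25,0.996
12,circ3.5,0.903
12,5x5,1.019
12,10x10,1.016
12,circ14,0.999
12,20x20,1
12,circ25,0.999
13,circ3.5,0.656
13,5x5,0.982
13,10x10,1
13,circ14,1
13,20x20,1
13,circ25,1
15,circ3.5,0.7
15,5x5,0.971
15,10x10,1
15,circ14,1
15,20x20,1
15,circ25,1
17,circ3.5,0.778
17,5x5,0.984
17,10x10,1
17,circ14,1
17,20x20,1
17,circ25,1
18,circ3.5,0.758
18,5x5,0.989
18,10x10,1
18,circ14,1
18,20x20,1
18,circ25,1
20,circ3.5,0.938
20,5x5,1.003
20,10x10,1
20,circ14,1
20,20x20,1
20,circ25,1
24,circ3.5,1.015
24,5x5,1.011
24,10x10,1
24,circ14,1
24,20x20,1
24,circ25,1
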