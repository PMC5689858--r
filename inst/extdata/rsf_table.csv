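option,R,M,factor,placeholder
1,25,2,1,FALSE
1,23.8,2,0.9914,FALSE
1,22.6,2,0.9823,FALSE
1,25,10,1,FALSE
1,23.8,10,0.9931,FALSE
1,22.6,10,0.9855,FALSE
1,25,20,1,FALSE
1,23.8,20,0.9895,FALSE
1,22.6,20,0.9772,FALSE
13,32,2,1,FALSE
13,30.8,2,1.0011,FALSE
13,29.6,2,1.0018,FALSE
13,32,5,1,FALSE
13,30.8,5,1.001,FALSE
13,29.6,5,1.0014,FALSE
13,32,10,1,FALSE
13,30.8,10,1.0001,FALSE
13,29.6,10,0.9994,FALSE
20,15.3,2,1,FALSE
20,14.3,2,0.9729,FALSE
20,13.3,2,0.945,FALSE
20,15.3,10,1,FALSE
20,14.3,10,0.968,FALSE
20,13.3,10,0.9336,FALSE
20,15.3,13.3,1,FALSE
20,14.3,13.3,0.9589,FALSE
20,13.3,13.3,0.9116,FALSE
20,15.3,14.3,1,FALSE
20,14.3,14.3,0.9535,FALSE
20,13.3,14.3,0.9196,TRUE
20,15.3,15.3,1,FALSE
20,14.3,15.3,0.9665,TRUE
20,13.3,15.3,0.9251,TRUE
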