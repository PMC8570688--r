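K,A,S,A0,alpha,S0,beta
0,40,500,40,0,500,0
10,30,500,30,30,500,0
20,20,500,20,20,500,0
30,0,500,0,0,500,0
50,0,600,0,0,500,250
90,0,700,0,0,600,200
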