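mix,ANT,BEN,ANT_impA,PABA
1,7.0,3.0,1.5,0.75
2,7.0,1.0,1.0,0.25
3,9.0,3.0,1.0,1.25
4,7.0,2.0,2.5,0.5
5,8.0,4.0,1.5,1.25
6,9.0,4.0,2.5,0.25
7,9.0,1.0,0.5,0.75
8,7.0,4.0,0.5,1.0
9,5.0,4.0,1.0,0.5
10,8.0,2.0,1.0,0.75
11,6.0,3.0,0.5,0.5
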