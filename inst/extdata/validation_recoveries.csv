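mix,component,model,actual,recovery
1,ANT,PLS,7,98.26
1,ANT,ANN,7,99.98
1,ANT,MCR-ALS,7,101.29
1,BEN,PLS,3,103.73
1,BEN,ANN,3,98.66
1,BEN,MCR-ALS,3,102.35
1,ANT_impA,PLS,1.5,103.49
1,ANT_impA,ANN,1.5,99.97
1,ANT_impA,MCR-ALS,1.5,100.15
1,PABA,PLS,0.75,102.26
1,PABA,ANN,0.75,101.66
1,PABA,MCR-ALS,0.75,104.95
2,ANT,PLS,7,97.15
2,ANT,ANN,7,100.02
2,ANT,MCR-ALS,7,103.63
2,BEN,PLS,1,101.45
2,BEN,ANN,1,98.78
2,BEN,MCR-ALS,1,100.85
2,ANT_impA,PLS,1,99.97
2,ANT_impA,ANN,1,99.95
2,ANT_impA,MCR-ALS,1,103.77
2,PABA,PLS,0.25,101.52
2,PABA,ANN,0.25,101.10
2,PABA,MCR-ALS,0.25,101.76
3,ANT,PLS,9,97.63
3,ANT,ANN,9,101.00
3,ANT,MCR-ALS,9,97.53
3,BEN,PLS,3,102.64
3,BEN,ANN,3,101.41
3,BEN,MCR-ALS,3,99.59
3,ANT_impA,PLS,1,100.82
3,ANT_impA,ANN,1,100.07
3,ANT_impA,MCR-ALS,1,103.10
3,PABA,PLS,1.25,97.02
3,PABA,ANN,1.25,99.88
3,PABA,MCR-ALS,1.25,95.98
4,ANT,PLS,7,99.08
4,ANT,ANN,7,99.99
4,ANT,MCR-ALS,7,101.16
4,BEN,PLS,2,102.22
4,BEN,ANN,2,101.04
4,BEN,MCR-ALS,2,102.84
4,ANT_impA,PLS,2.5,103.00
4,ANT_impA,ANN,2.5,100.02
4,ANT_impA,MCR-ALS,2.5,103.30
4,PABA,PLS,0.5,98.47
4,PABA,ANN,0.5,98.66
4,PABA,MCR-ALS,0.5,100.42
5,ANT,PLS,8,97.37
5,ANT,ANN,8,100.02
5,ANT,MCR-ALS,8,101.76
5,BEN,PLS,4,98.29
5,BEN,ANN,4,99.68
5,BEN,MCR-ALS,4,103.84
5,ANT_impA,PLS,1.5,99.96
5,ANT_impA,ANN,1.5,99.97
5,ANT_impA,MCR-ALS,1.5,99.99
5,PABA,PLS,1.25,99.25
5,PABA,ANN,1.25,101.25
5,PABA,MCR-ALS,1.25,100.73
6,ANT,PLS,9,98.85
6,ANT,ANN,9,101.00
6,ANT,MCR-ALS,9,101.63
6,BEN,PLS,4,99.28
6,BEN,ANN,4,99.95
6,BEN,MCR-ALS,4,101.45
6,ANT_impA,PLS,2.5,98.44
6,ANT_impA,ANN,2.5,99.99
6,ANT_impA,MCR-ALS,2.5,101.08
6,PABA,PLS,0.25,99.93
6,PABA,ANN,0.25,101.22
6,PABA,MCR-ALS,0.25,103.46
7,ANT,PLS,9,97.03
7,ANT,ANN,9,102.02
7,ANT,MCR-ALS,9,99.82
7,BEN,PLS,1,97.24
7,BEN,ANN,1,101.18
7,BEN,MCR-ALS,1,98.10
7,ANT_impA,PLS,0.5,100.09
7,ANT_impA,ANN,0.5,99.98
7,ANT_impA,MCR-ALS,0.5,97.12
7,PABA,PLS,0.75,97.27
7,PABA,ANN,0.75,99.09
7,PABA,MCR-ALS,0.75,98.68
8,ANT,PLS,7,100.93
8,ANT,ANN,7,99.97
8,ANT,MCR-ALS,7,98.54
8,BEN,PLS,4,101.84
8,BEN,ANN,4,99.39
8,BEN,MCR-ALS,4,100.38
8,ANT_impA,PLS,0.5,98.67
8,ANT_impA,ANN,0.5,99.99
8,ANT_impA,MCR-ALS,0.5,98.94
8,PABA,PLS,1,98.61
8,PABA,ANN,1,101.80
8,PABA,MCR-ALS,1,97.16
9,ANT,PLS,5,102.87
9,ANT,ANN,5,100.04
9,ANT,MCR-ALS,5,96.70
9,BEN,PLS,4,100.42
9,BEN,ANN,4,100.42
9,BEN,MCR-ALS,4,102.83
9,ANT_impA,PLS,1,102.39
9,ANT_impA,ANN,1,99.99
9,ANT_impA,MCR-ALS,1,102.62
9,PABA,PLS,0.5,101.08
9,PABA,ANN,0.5,97.80
9,PABA,MCR-ALS,0.5,101.30
10,ANT,PLS,8,96.72
10,ANT,ANN,8,98.96
10,ANT,MCR-ALS,8,101.65
10,BEN,PLS,2,101.70
10,BEN,ANN,2,98.59
10,BEN,MCR-ALS,2,98.89
10,ANT_impA,PLS,1,100.58
10,ANT_impA,ANN,1,100.00
10,ANT_impA,MCR-ALS,1,98.15
10,PABA,PLS,0.75,100.48
10,PABA,ANN,0.75,102.60
10,PABA,MCR-ALS,0.75,100.16
11,ANT,PLS,6,99.35
11,ANT,ANN,6,99.99
11,ANT,MCR-ALS,6,99.11
11,BEN,PLS,3,99.69
11,BEN,ANN,3,100.85
11,BEN,MCR-ALS,3,98.17
11,ANT_impA,PLS,0.5,99.90
11,ANT_impA,ANN,0.5,100.10
11,ANT_impA,MCR-ALS,0.5,102.14
11,PABA,PLS,0.5,97.65
11,PABA,ANN,0.5,98.00
11,PABA,MCR-ALS,0.5,97.28
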