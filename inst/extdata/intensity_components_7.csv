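binders,mean,sd,weight
0,57.17,34.73,0.12
1,150.75,42.07,0.21
2,198.26,50.68,0.20
3,254.73,60.71,0.15
4,314.23,69.58,0.14
5,401.37,85.73,0.11
6,551.86,111.40,0.07
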