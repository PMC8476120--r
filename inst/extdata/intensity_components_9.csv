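binders,mean,sd,weight
0,24.52,35.58,0.10
1,138.57,41.54,0.15
2,173.87,46.04,0.16
3,210.90,51.35,0.16
4,264.22,55.51,0.14
5,322.20,62.04,0.11
6,382.67,80.58,0.08
7,490.73,72.01,0.05
8,652.38,91.13,0.04
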