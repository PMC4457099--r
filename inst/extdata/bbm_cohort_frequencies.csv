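gene,panel,freq_bbm,freq_primary
GALNT9,array,55,0
HOXD3,literature,100,81
CCDC8,literature,73,40
HOXB13,literature,80,53
ABCB1,literature,80,68
PENK,literature,80,79
BNC1,literature,71,17
PCDH8,literature,73,54
STAT3,literature,67,57
TNFRSF10D,literature,60,75
WIF1,literature,53,55
CLDN18,emt,100,100
KRT85,emt,100,100
MIR127,emt,100,100
MIR433,emt,100,100
MIR23B,emt,92,60
KRT83,emt,84,100
MST1R,emt,78,60
BVES,emt,64,60
CLDN6,emt,55,50
HOXD10,emt,55,55
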