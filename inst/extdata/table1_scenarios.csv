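dose_mbq,T1,T2,T3,T4,T5,A1,A2,A3,A4
1.5,0.100,0.100,0.100,0.300,0.400,0.300,0.200,0.100,0.100
2.5,0.120,0.130,0.200,0.400,0.450,0.400,0.300,0.150,0.120
3.5,0.140,0.160,0.300,0.450,0.500,0.500,0.400,0.200,0.140
4.5,0.160,0.200,0.400,0.500,0.550,0.500,0.500,0.300,0.160
6.0,0.180,0.250,0.500,0.550,0.600,0.500,0.600,0.500,0.180
7.0,0.200,0.400,0.600,0.600,0.650,0.500,0.700,0.700,0.200
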