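vowel,gender,formant,mean_hz,std_hz
a,M,F1,420.48,13.57
e,M,F1,358.12,6.03
schwa,M,F1,333.12,2.72
i,M,F1,228.99,0.6
o,M,F1,371.59,5.26
u,M,F1,326.49,5.21
a,F,F1,767.95,12.25
e,F,F1,692.99,7.03
schwa,F,F1,654.43,2.34
i,F,F1,490.61,0.04
o,F,F1,620.58,5.65
u,F,F1,502.72,4.86
a,M,F2,1231.05,25.17
e,M,F2,1578.04,24.33
schwa,M,F2,1324.39,50.29
i,M,F2,1738.69,4.63
o,M,F2,918.09,2.03
u,M,F2,754.98,25.44
a,F,F2,1562.41,27.54
e,F,F2,2059.27,22.54
schwa,F,F2,1711.98,48.65
i,F,F2,2624.81,4.21
o,F,F2,1245.83,2.38
u,F,F2,1157.55,23.76
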