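time,dose_Gy,t43
0,2,0
24,2,0
48,2,0
72,2,0
96,2,0
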