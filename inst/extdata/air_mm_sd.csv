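0.000,0.009,0.011,0.022
0.024,0.022,0.025,0.049
0.019,0.018,0.025,0.042
0.014,0.010,0.012,0.031
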