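0.000,0.009,0.011,0.029
0.029,0.032,0.026,0.063
0.054,0.024,0.026,0.078
0.016,0.019,0.018,0.036
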