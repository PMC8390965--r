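1.000,0.003,-0.009,0.012
-0.005,0.999,-0.002,-0.008
0.011,0.007,1.002,-0.011
0.007,-0.009,0.004,1.014
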