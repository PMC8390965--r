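1.000,0.012,-0.005,0.071
-0.012,1.023,-0.222,-0.327
0.007,0.376,0.678,1.022
-0.023,0.055,-0.342,0.562
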