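rotation_deg,method,R_deg,alpha_deg
0,lc,45.4,-68.6
45,lc,58.7,-20.4
90,lc,59.6,16.3
135,lc,60.9,55.8
180,lc,64.6,104.4
0,rcp_phasor,69.9,-69.2
45,rcp_phasor,51.2,-38.2
90,rcp_phasor,62.3,9.3
135,rcp_phasor,56.1,51.9
180,rcp_phasor,71.9,95.6
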