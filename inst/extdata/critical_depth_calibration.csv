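concentration_g_per_L,critical_depth_cm
0.28,5
0.85,2
1.7,1
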