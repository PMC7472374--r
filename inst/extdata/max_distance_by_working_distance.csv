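working_distance_mm,max_ratio_mm
60,0.24
65,0.27
70,0.32
75,0.34
80,0.38
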