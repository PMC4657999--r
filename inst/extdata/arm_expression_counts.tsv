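library	both_arms	precursors_detected
LV	51	95
GL	86	161
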