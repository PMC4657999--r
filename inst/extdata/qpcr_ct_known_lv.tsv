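assay	ct	sd
miR-21-5p	26.25	0.221885857
miR-493-5p	34.25	0.41585374
miR-493-4p	21.73	1.291861135
miR-133-3p	14.44	2.278697632
U6	18.59	1.383107503
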