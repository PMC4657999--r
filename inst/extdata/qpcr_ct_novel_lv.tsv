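assay	ct	sd
miR-146b-5p	33.129	0.398256617
miR-151-5p	26.257	0.634608124
miR-378-3p	20.907	0.181923092
miR-423-5p	29.107	0.114140675
miR-145-5p	27.725	0.284937142
miR-222-3p	30.578	0.713898269
miR-330-3p	30.898	0.977237439
miR-324-5p	26.172	1.767929513
miR-2285x-3p	28.181	0.25621647
miR-4005-5p	28.181	0.25621647
U6	25.338	0.144719684
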