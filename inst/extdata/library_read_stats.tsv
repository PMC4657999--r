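library	raw_reads	mappable_reads	mature_mapped_reads	novel_mapped_reads	known_mapped_reads
LV	9512054	5537088	3927458	1607604	2319350
GL	11831013	9089864	6663266	1900117	4762811
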