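mirna	target_gene
hsa-miR-101-3p	VEGFA
hsa-miR-101-3p	VEGFC
hsa-miR-130b-5p	VEGFB
hsa-miR-940	VEGFB
hsa-miR-218-5p	VEGFC
hsa-miR-335-5p	VEGFD
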