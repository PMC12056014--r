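chrom	pos	tissue	m
1	120345	cortex	0.97
1	120345	hippocampus	0.42
1	120345	whole_blood	0.90
1	455901	cortex	0.90
1	455901	liver	0.13
2	88012	cortex	1.00
2	88012	thyroid	0.88
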