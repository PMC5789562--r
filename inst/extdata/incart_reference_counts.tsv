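record	total_beats	tp	fp	fn	sen	ppr	der	acc
overall	175914	175660	189	254	99.86	99.89	0.25	99.75
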