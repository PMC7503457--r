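mirna_id	target_id	target_class
M1	L1	lncRNA
M1	G1	mRNA
M3	L2	lncRNA
M3	G4	mRNA
M4	L2	lncRNA
M4	G3	mRNA
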