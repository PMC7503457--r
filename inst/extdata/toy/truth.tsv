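lnc_id	mir_id	mrna_id
L1	M1	G1
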