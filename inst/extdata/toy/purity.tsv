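sample_id	purity
s01	0.95
s02	0.95
s03	0.95
s04	0.95
s05	0.95
s06	0.95
s07	0.95
s08	0.95
s09	0.85
s10	0.85
s11	0.85
s12	0.85
s13	0.85
s14	0.85
s15	0.85
s16	0.85
s17	0.8
s18	0.75
s19	0.5
s20	0.8
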