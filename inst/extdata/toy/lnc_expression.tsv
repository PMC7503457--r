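gene_id	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20
L1	9.5	9	8.5	8	5	5.1	5.2	5.3	5.4	5.5	5.6	5.7	1.9	1.8	1.7	1.6	5	5	5	5
L2	2	4	2.5	4.5	3	5	2.2	4.2	2.7	4.7	3.2	5.2	2.4	4.4	2.9	4.9	5	5	5	5
L3	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	2	3	4	5	5	5	5	5
L4	5	5.4	5	5.4	5	5.4	5	5.4	5	5.4	5	5.4	5	5.4	5	5.4	5	5	5	5
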