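gene_id	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20
M1	1	1.1	1.2	1.3	3	3.1	3.2	3.3	3.4	3.5	3.6	3.7	5	5.2	5.4	5.6	5	5	5	5
M2	6	6	6	6	6	6	6	6	6	6	6	6	6	6	6	6	5	5	5	5
M3	1.5	2.5	3.5	4.5	1.5	2.5	3.5	4.5	1.5	2.5	3.5	4.5	1.5	2.5	3.5	4.5	5	5	5	5
M4	2	2.1	2.2	2.3	2.4	2.5	2.6	2.7	2.8	2.9	3	3.1	3.2	3.3	3.4	3.5	5	5	5	5
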