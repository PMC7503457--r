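gene_id	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20
G1	8	8.2	8.1	8.3	6.7	6.6	6.5	6.4	6.3	6.2	6.1	6	4	3.6	3.8	3	5	5	5	5
G2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	2	3	4	5	5	5	5
G3	3.8	4.5	3.3	4.2	3.1	4	4.6	3.5	4.4	3.2	4.1	3.7	4.3	3.4	3.9	3.6	5	5	5	5
G4	3.5	4.5	5.5	6.5	3.5	4.5	5.5	6.5	3.5	4.5	5.5	6.5	3.5	4.5	5.5	6.5	5	5	5	5
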