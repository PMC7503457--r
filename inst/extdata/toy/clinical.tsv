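sample_id	time	event
s01	150	1
s02	300	0
s03	450	1
s04	600	0
s05	750	1
s06	900	0
s07	1050	1
s08	1200	0
s09	1350	1
s10	1500	0
s11	1650	1
s12	1800	0
s13	1950	1
s14	2100	0
s15	2250	1
s16	2400	0
s17	2550	1
s18	2700	0
s19	2850	1
s20	3000	0
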