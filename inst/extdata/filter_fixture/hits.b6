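S1_Read01	REF_X	87.0	380	49	0	10	380	280	690	0	722
S1_Read02	REF_X	99.0	379	4	0	1	379	300	700	0	720
S1_Read03	REF_X	99.0	450	5	0	1	450	300	700	0	855
S1_Read04	REF_X	99.0	451	5	0	1	451	300	700	0	857
S1_Read05	REF_X	99.0	400	4	0	1	400	300	700	0	760
S1_Read06	REF_X	86.9	400	52	0	1	400	300	700	0	760
S1_Read07	REF_X	99.0	379	4	0	1	400	300	700	0	720
S1_Read08	REF_X	99.0	400	4	0	11	400	300	700	0	760
S1_Read09	REF_X	99.0	400	4	0	1	379	300	700	0	760
S1_Read10	REF_X	99.0	400	4	0	1	400	279	700	0	760
S2_Read11	REF_X	99.0	400	4	0	1	400	380	700	0	760
S2_Read12	REF_X	99.0	400	4	0	1	400	381	700	0	760
S2_Read13	REF_X	99.0	400	4	0	1	400	300	689	0	760
S2_Read14	REF_X	99.0	400	4	0	1	400	300	690	0	760
S2_Read15	REF_X	80.0	400	80	0	1	400	300	700	0	760
S2_Read15	REF_X	99.0	400	4	0	1	400	300	700	0	760
S2_Read17	REF_X	100.0	400	0	0	1	400	300	700	0	760
S2_Read18	REF_X	99.0	400	4	0	1	400	300	700	0	760
S2_Read19	REF_X	86.5	400	54	0	1	400	300	700	0	760
S2_Read19	REF_X	99.0	400	4	0	12	400	300	700	0	760
S2_Read20	REF_X	99.0	400	4	0	1	400	300	700	0	760
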