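read_id	length	pass_length	pass_alignment	retained
S1_Read01	380	TRUE	TRUE	TRUE
S1_Read02	379	FALSE	FALSE	FALSE
S1_Read03	450	TRUE	TRUE	TRUE
S1_Read04	451	FALSE	TRUE	FALSE
S1_Read05	400	FALSE	TRUE	FALSE
S1_Read06	400	TRUE	FALSE	FALSE
S1_Read07	400	TRUE	FALSE	FALSE
S1_Read08	400	TRUE	FALSE	FALSE
S1_Read09	400	TRUE	FALSE	FALSE
S1_Read10	400	TRUE	FALSE	FALSE
S2_Read11	400	TRUE	TRUE	TRUE
S2_Read12	400	TRUE	FALSE	FALSE
S2_Read13	400	TRUE	FALSE	FALSE
S2_Read14	400	TRUE	TRUE	TRUE
S2_Read15	400	TRUE	TRUE	TRUE
S2_Read16	400	TRUE	FALSE	FALSE
S2_Read17	400	TRUE	TRUE	TRUE
S2_Read18	400	TRUE	TRUE	TRUE
S2_Read19	400	TRUE	FALSE	FALSE
S2_Read20	400	TRUE	TRUE	TRUE
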