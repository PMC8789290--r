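label	cargo_a	cargo_b	n_a	n_b	n_co	duration_s	n_flagella	p_a_printed	p_b_printed	p_obs_printed	p_calc_printed
pf14 armc2 RSP3-NG ARMC2-mS (full length)	ARMC2-mS	RSP3-NG	125	42	26	1504	17	0.083	0.028	0.017	0.0023
pf14 armc2 RSP3-NG ARMC2-mS (regenerating)	ARMC2-mS	RSP3-NG	578	130	104	1622	20	0.36	0.08	0.064	0.029
ida3 armc2 IDA3-NG ARMC2-mS (regenerating)	ARMC2-mS	IDA3-NG	243	106	20	905	35	0.27	0.12	0.022	0.03
oda3 oda6 armc2 IC2-NG ARMC2-mS (regenerating)	ARMC2-mS	IC2-NG	82	78	3	1575	20	0.052	0.049	0.0019	0.0026
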