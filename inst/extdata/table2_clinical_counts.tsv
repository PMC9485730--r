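item	level	count	percent
sex	Female	33	18.44
sex	Male	146	81.56
tobacco	Yes	114	63.69
tobacco	No	65	36.31
alcohol	Yes	106	59.22
alcohol	No	73	40.78
t_stage	T1	12	6.7
t_stage	T2	27	15.08
t_stage	T3	110	61.45
t_stage	T4	30	16.76
n_stage	N0	83	46.37
n_stage	N1	62	34.64
n_stage	N2	22	12.29
n_stage	N3	12	6.7
tnm_stage	Stage I	10	5.59
tnm_stage	Stage II	77	43.02
tnm_stage	Stage III	92	51.4
grade	Poorly	49	27.37
grade	Moderately	98	54.75
grade	Well	32	17.88
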