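strain	group	genome_type	modified_genome_type	n_snp	n_psnp	n_total	copy_number	copy_number_se
W303	OM	Mosaic	Mosaic	0	3	3	182	0.142
L_1374	W/E	Structured	Structured mosaic	6	2	8	60	0.096
DBVPG 1106	W/E	Structured	Structured mosaic	7	1	8	98	0.112
DBVPG 1788	W/E	Structured	Structured mosaic	8	0	8	67	0.101
YJM981	W/E	Structured	Structured mosaic	6	3	9	354	0.495
YJM975	W/E	Structured	Structured mosaic	6	4	10	65	0.095
YJM978	W/E	Structured	Structured mosaic	6	4	10	65	0.136
YPS128	NA	Structured	Structured clean	14	0	14	62	0.094
S288c	OM	Mosaic	Mosaic	0	14	14	111	0.163
BC187	W/E	Structured	Structured mosaic	7	7	14	71	0.135
DBVPG 1373	W/E	Structured	Structured mosaic	8	7	15	75	0.127
DBVPG 6765	W/E	Structured	Structured mosaic	13	3	16	70	0.077
YPS606	NA	Structured	Structured clean	14	2	16	67	0.096
NCYC 110	WA +	Structured	Structured clean	15	2	17	163	0.199
DBVPG 6044	WA +	Structured	Structured clean	15	2	17	107	0.121
Y9	SA	Structured	Structured mosaic	8	10	18	79	0.149
UWOPS87-2421	UM	Mosaic	Mosaic	14	4	18	57	0.109
322134S	OM	Mosaic	Mosaic	6	12	18	109	0.140
SK1	WA +	Mosaic	Mosaic	16	3	19	72	0.080
27361N	OM	Mosaic	Mosaic	4	15	19	93	0.119
Y12	SA	Structured	Structured mosaic	9	11	20	78	0.143
378604X	OM	Mosaic	Mosaic	0	20	20	87	0.117
Y55	WA +	Mosaic	Mosaic	15	7	22	72	0.060
K11	SA	Structured	Structured mosaic	23	2	25	50	0.082
YIIc17_E5	YII	Mosaic	Mosaic	7	18	25	80	0.117
DBVPG 6040	OM	Mosaic	Mosaic	0	27	27	132	0.106
NCYC 361	OM	Mosaic	Mosaic	0	27	27	189	0.189
YS9	OM	Mosaic	Mosaic	1	27	28	56	0.130
UWOPS83-787-3	UM	Mosaic	Mosaic	8	21	29	64	0.102
UWOPS03-461-4	MA	Structured	Structured clean	29	0	29	89	0.090
UWOPS05-217-3	MA	Structured	Structured clean	27	3	30	133	0.186
UWOPS05-227-2	MA	Structured	Structured clean	24	7	31	70	0.108
YS4	OM	Mosaic	Mosaic	9	24	33	88	0.110
DBVPG 1853	OM	Mosaic	Mosaic	14	23	37	144	0.205
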