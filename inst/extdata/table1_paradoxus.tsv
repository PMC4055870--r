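strain	group	n_snp	n_psnp	n_total	copy_number	copy_number_se
Q32.3	European	0	0	0	74	0.109
Q89.8	European	0	0	0	81	0.228
Q95.3	European	0	0	0	46	0.093
S36.7	European	0	0	0	57	0.109
T21.4	European	0	0	0	66	0.074
Y6.5	European	1	0	1	65	0.085
Y7.2	European	1	0	1	78	0.108
Z1.1	European	1	0	1	83	0.103
Q62.5	European	2	2	4	68	0.096
CBS 432 (T)	European	5	0	5	68	0.072
Q59.1	European	0	5	5	52	0.062
DBVPG 4650	European	2	4	6	87	0.107
KPN 3828	European	7	1	8	82	0.112
KPN 3829	European	7	1	8	79	0.124
CBS 5829	European	6	3	9	88	0.095
N-17	European	1	17	18	78	0.068
IFO 1804	Far Eastern	39	0	39	96	0.187
N-44	Far Eastern	38	1	39	52	0.085
N-45	Far Eastern	4	36	40	66	0.049
N-43	Far Eastern	40	1	41	64	0.126
A12	American	84	0	84	45	0.065
A4	American	88	0	88	66	0.098
UFRJ 50816	American	92	0	92	72	0.090
UFRJ 50791	American	95	0	95	64	0.107
YPS138	American	95	0	95	76	0.099
DBVPG 6304	American	97	2	99	53	0.094
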