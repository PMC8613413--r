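cohort	rmt_pct_mso	dlpfc_pct_mso	dlpfc_pct_rmt	lpc_pct_mso	lpc_pct_rmt
1	35	35	100	35	100
1	37	40	108	45	122
1	38	45	118	45	118
1	39	41	105	38	97
1	42	41	98	46	110
1	43	30	70	50	116
1	44	39	89	46	105
1	45	39	87	41	91
1	47	35	74	49	104
1	48	42	88	48	100
1	51	52	102	39	76
1	57	39	68	50	88
1	58	48	83	65	112
1	77	37	48	79	103
1	77	35	45	36	47
2	40	34	85	44	110
2	44	36	82	57	130
2	45	33	73	40	89
2	47	31	66	32	68
2	51	48	94	56	110
2	55	33	60	35	64
2	56	47	84	42	75
2	58	49	85	69	119
2	58	41	71	54	93
2	59	44	75	55	93
2	66	39	59	49	74
2	72	37	51	47	65
2	81	40	49	45	56
2	83	45	54	47	57
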