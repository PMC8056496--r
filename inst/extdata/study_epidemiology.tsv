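variable	level	cases	controls	unit	n_cases	n_controls	p_printed
age	mean	62.46	56.62	years	78	256	0.0842
age	median	62	57	years	78	256	NA
sex	male	41	43	percent	78	256	0.956
sex	female	59	57	percent	78	256	NA
ancestry	African	32	17.5	percent	78	256	0.1303
ancestry	European	66.7	81.3	percent	78	256	NA
ancestry	Asian	1.3	1.2	percent	78	256	NA
tobacco	yes	51.32	32.31	percent	76	260	0.002
tobacco	no	48.68	67.69	percent	76	260	NA
alcohol	yes	31.58	32.31	percent	76	260	0.7774
alcohol	no	68.42	67.69	percent	76	260	NA
diabetes	yes	35.53	9.62	percent	76	260	0.0001
diabetes	no	64.47	90.38	percent	76	260	NA
pancreatitis	yes	10.53	0.77	percent	76	260	0.0001
pancreatitis	no	89.47	99.23	percent	76	260	NA
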