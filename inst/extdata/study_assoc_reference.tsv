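rsid	gene	maf_controls	maf_cases	or_allelic	or_allelic_low	or_allelic_high	p_allelic	p_trend	significant
rs11655237	LINC00673	0.13	0.14	1.06	0.63	1.79	0.806	0.795	FALSE
rs2736098	TERT	0.25	0.22	0.79	0.51	1.22	0.302	0.361	FALSE
rs351365	WNT2B	0.29	0.26	0.85	0.57	1.28	0.454	0.449	FALSE
rs3790844	NR5A2	0.27	0.18	0.61	0.38	0.96	0.036	0.030	TRUE
rs1486134	ETAA1	0.25	0.24	1.03	0.68	1.55	0.867	0.838	FALSE
rs16986825	ZNRF3	0.17	0.14	0.76	0.45	1.28	0.309	0.318	FALSE
rs17688601	SUGCT	0.25	0.18	0.63	0.40	1.00	0.046	0.093	TRUE
rs9581943	PDX1	0.36	0.31	1.22	0.84	1.78	0.282	0.270	FALSE
rs1561927	MIR1208	0.24	0.32	1.47	0.99	2.17	0.058	0.050	FALSE
rs9854771	TP63	0.39	0.25	0.53	0.35	0.80	0.003	0.002	TRUE
rs73328514	TNS3	0.10	0.15	1.56	0.90	2.70	0.112	0.098	FALSE
rs7310409	HNF1A	0.41	0.49	1.41	0.98	2.00	0.065	0.061	TRUE
rs1517037	GRP	0.21	0.24	1.18	0.76	1.82	0.449	0.434	FALSE
rs2853677	TERT	0.46	0.37	0.70	0.48	1.02	0.068	0.051	FALSE
rs2941471	HNF4G	0.44	0.35	0.64	0.43	0.94	0.026	0.037	TRUE
rs6971499	LINC-PINT	0.11	0.10	1.24	0.67	2.29	0.485	0.523	FALSE
rs10991043	SMC2	0.39	0.37	1.10	0.76	1.60	0.601	0.545	FALSE
rs401681	TERT	0.45	0.54	1.53	1.05	2.22	0.026	0.026	TRUE
rs13303010	NOC2L	0.22	0.37	1.88	1.29	2.77	0.001	0.003	TRUE
rs9543325	13q22.1	0.44	0.56	1.66	1.15	2.38	0.007	0.011	TRUE
rs4795218	HNF1B	0.20	0.11	0.53	0.31	0.90	0.021	0.015	TRUE
rs7190458	BCAR1	0.07	0.08	0.88	0.42	1.87	0.755	0.657	FALSE
rs10094872	MYC	0.28	0.34	1.37	0.92	2.02	0.111	0.145	FALSE
rs684559	CHI3L2	0.32	0.29	1.24	0.84	1.81	0.270	0.448	FALSE
rs353630	CD44	0.29	0.30	0.95	0.64	1.39	0.806	0.848	FALSE
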