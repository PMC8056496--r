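rsid	ancestry	maf_dbsnp	n_dbsnp	maf_cases	n_cases	maf_controls	n_controls	sig_case_vs_control	sig_control_vs_dbsnp
rs3790844	African	0.13	6740	0.23	30	0.26	45	FALSE	TRUE
rs3790844	European	0.23	158742	0.21	62	0.26	206	FALSE	FALSE
rs3790844	Asian	0.66	414	1.00	2	0.88	4	FALSE	FALSE
rs17688601	African	0.07	2012	0.22	30	0.27	45	FALSE	TRUE
rs17688601	European	0.26	119368	0.18	62	0.25	206	FALSE	FALSE
rs17688601	Asian	0.05	280	0.00	2	0.00	4	FALSE	FALSE
rs9854771	African	0.28	3086	0.23	30	0.47	45	TRUE	TRUE
rs9854771	European	0.36	93526	0.27	62	0.38	206	FALSE	FALSE
rs9854771	Asian	0.14	238	0.00	2	0.00	4	FALSE	FALSE
rs7310409	African	0.32	6064	0.48	30	0.34	45	FALSE	FALSE
rs7310409	European	0.40	153574	0.47	62	0.42	206	FALSE	FALSE
rs7310409	Asian	0.38	370	0.50	2	0.25	4	FALSE	FALSE
rs2941471	African	0.13	82	0.65	30	0.41	45	TRUE	TRUE
rs2941471	European	0.42	2072	0.67	62	0.44	206	TRUE	FALSE
rs2941471	Asian	0.50	4	0.50	2	0.375	4	FALSE	FALSE
rs401681	African	NA	NA	0.42	30	0.45	45	FALSE	FALSE
rs401681	European	NA	NA	0.50	62	0.45	206	FALSE	FALSE
rs401681	Asian	NA	NA	0.50	2	0.25	4	FALSE	FALSE
rs13303010	African	0.64	3306	0.35	30	0.35	45	FALSE	TRUE
rs13303010	European	0.10	117068	0.33	62	0.19	206	TRUE	FALSE
rs13303010	Asian	0.27	186	0.25	2	0.25	4	FALSE	FALSE
rs9543325	African	0.85	5580	0.45	30	0.61	45	TRUE	TRUE
rs9543325	European	0.37	153016	0.49	62	0.40	206	FALSE	FALSE
rs9543325	Asian	0.46	370	0.25	2	0.50	4	FALSE	FALSE
rs4795218	African	0.06	82	0.13	30	0.14	45	FALSE	FALSE
rs4795218	European	0.21	2072	0.15	62	0.22	206	FALSE	FALSE
rs4795218	Asian	0.50	4	0.00	2	0.20	4	FALSE	FALSE
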