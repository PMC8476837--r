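metabolite	method	n_snp	pval	or_	ci_low	ci_high	p_heterogeneity	p_pleiotropy
4-vinylphenol sulfate	MR-Egger	10	1.69e-01	1.29	0.93	1.79	0.61	0.74
4-vinylphenol sulfate	WeightedMedian	10	3.34e-03	1.29	1.09	1.53	NA	NA
4-vinylphenol sulfate	IVW	10	2.16e-03	1.22	1.07	1.38	0.7	NA
4-vinylphenol sulfate	SimpleMode	10	8.70e-02	1.31	0.99	1.72	NA	NA
4-vinylphenol sulfate	WeightedMode	10	2.37e-02	1.34	1.09	1.66	NA	NA
Linolenate [alpha or gamma; (18:3n3 or 6)]	MR-Egger	3	2.93e-01	2.45	1.03	5.86	0.27	0.53
Linolenate [alpha or gamma; (18:3n3 or 6)]	WeightedMedian	3	8.30e-03	1.88	1.18	3.01	NA	NA
Linolenate [alpha or gamma; (18:3n3 or 6)]	IVW	3	6.31e-03	1.71	1.16	2.52	0.33	NA
Linolenate [alpha or gamma; (18:3n3 or 6)]	SimpleMode	3	1.36e-01	1.91	1.13	3.22	NA	NA
Linolenate [alpha or gamma; (18:3n3 or 6)]	WeightedMode	3	1.22e-01	1.90	1.17	3.07	NA	NA
Oleoylcarnitine	MR-Egger	7	6.03e-01	1.81	0.22	14.86	0.78	0.91
Oleoylcarnitine	WeightedMedian	7	6.02e-02	1.54	0.98	2.40	NA	NA
Oleoylcarnitine	IVW	7	8.06e-03	1.60	1.13	2.28	0.87	NA
Oleoylcarnitine	SimpleMode	7	4.14e-01	1.36	0.68	2.73	NA	NA
Oleoylcarnitine	WeightedMode	7	3.66e-01	1.40	0.71	2.75	NA	NA
Isoleucine	MR-Egger	16	2.02e-01	3.11	0.59	16.39	0.51	0.62
Isoleucine	WeightedMedian	16	2.29e-01	1.67	0.72	3.84	NA	NA
Isoleucine	IVW	16	1.11e-02	2.08	1.18	3.67	0.57	NA
Isoleucine	SimpleMode	16	7.23e-01	1.33	0.28	6.20	NA	NA
Isoleucine	WeightedMode	16	7.92e-01	1.20	0.31	4.65	NA	NA
Cysteine-glutathione disulfide	MR-Egger	9	2.16e-01	0.60	0.29	1.25	0.89	0.41
Cysteine-glutathione disulfide	WeightedMedian	9	5.26e-02	0.82	0.67	1.00	NA	NA
Cysteine-glutathione disulfide	IVW	9	1.45e-02	0.82	0.71	0.96	0.89	NA
Cysteine-glutathione disulfide	SimpleMode	9	3.67e-01	0.86	0.62	1.18	NA	NA
Cysteine-glutathione disulfide	WeightedMode	9	1.98e-01	0.80	0.59	1.09	NA	NA
Glycodeoxycholate	MR-Egger	7	8.79e-01	1.03	0.72	1.46	0.29	0.46
Glycodeoxycholate	WeightedMedian	7	5.38e-02	0.89	0.79	1.00	NA	NA
Glycodeoxycholate	IVW	7	1.53e-02	0.90	0.82	0.98	0.33	NA
Glycodeoxycholate	SimpleMode	7	1.38e-01	0.87	0.73	1.02	NA	NA
Glycodeoxycholate	WeightedMode	7	2.22e-01	0.89	0.74	1.05	NA	NA
1-arachidonoylglycerophosphoethanolamine	MR-Egger	17	2.48e-02	0.29	0.11	0.77	0.96	0.07
1-arachidonoylglycerophosphoethanolamine	WeightedMedian	17	1.40e-02	0.60	0.40	0.90	NA	NA
1-arachidonoylglycerophosphoethanolamine	IVW	17	3.05e-02	0.72	0.54	0.97	0.83	NA
1-arachidonoylglycerophosphoethanolamine	SimpleMode	17	1.20e-01	0.54	0.26	1.13	NA	NA
1-arachidonoylglycerophosphoethanolamine	WeightedMode	17	6.72e-02	0.51	0.26	1.00	NA	NA
Phosphate	MR-Egger	4	2.14e-01	0.33	0.10	1.11	0.17	0.59
Phosphate	WeightedMedian	4	7.07e-02	0.44	0.18	1.07	NA	NA
Phosphate	IVW	4	3.40e-02	0.43	0.20	0.94	0.24	NA
Phosphate	SimpleMode	4	2.31e-01	0.39	0.11	1.34	NA	NA
Phosphate	WeightedMode	4	1.38e-01	0.43	0.19	0.98	NA	NA
Epiandrosterone sulfate	MR-Egger	3	3.94e-01	1.30	0.90	1.87	0.07	0.73
Epiandrosterone sulfate	WeightedMedian	3	1.34e-03	1.27	1.10	1.47	NA	NA
Epiandrosterone sulfate	IVW	3	4.31e-02	1.22	1.01	1.49	0.13	NA
Epiandrosterone sulfate	SimpleMode	3	2.36e-01	1.28	0.96	1.71	NA	NA
Epiandrosterone sulfate	WeightedMode	3	8.64e-02	1.27	1.10	1.47	NA	NA
Deoxycholate	MR-Egger	17	6.08e-01	1.07	0.83	1.37	0.41	0.72
Deoxycholate	WeightedMedian	17	2.18e-01	1.10	0.94	1.28	NA	NA
Deoxycholate	IVW	17	4.41e-02	1.11	1.00	1.24	0.47	NA
Deoxycholate	SimpleMode	17	2.74e-01	1.18	0.89	1.57	NA	NA
Deoxycholate	WeightedMode	17	3.11e-01	1.15	0.89	1.49	NA	NA
5-dodecenoate (12:1n7)	MR-Egger	11	2.28e-01	0.78	0.54	1.14	0.75	0.7
5-dodecenoate (12:1n7)	WeightedMedian	11	3.68e-02	0.78	0.61	0.98	NA	NA
5-dodecenoate (12:1n7)	IVW	11	4.95e-02	0.83	0.70	1.00	0.81	NA
5-dodecenoate (12:1n7)	SimpleMode	11	2.60e-01	0.79	0.53	1.17	NA	NA
5-dodecenoate (12:1n7)	WeightedMode	11	1.48e-01	0.79	0.60	1.06	NA	NA
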