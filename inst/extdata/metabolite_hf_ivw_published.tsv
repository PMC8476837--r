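id	metabolite	n_snp	beta	se	pval	or_	ci_low	ci_high
M36098	4-vinylphenol sulfate	10	0.20	0.06	2.16e-03	1.22	1.07	1.38
M35187	X-13429	4	0.27	0.09	3.10e-03	1.32	1.10	1.58
M34035	Linolenate [alpha or gamma; (18:3n3 or 6)]	3	0.54	0.20	6.31e-03	1.71	1.16	2.52
M34336	X-12726	22	0.12	0.05	7.15e-03	1.13	1.03	1.23
M35160	Oleoylcarnitine	7	0.47	0.18	8.06e-03	1.60	1.13	2.28
M34112	X-12544	18	-0.15	0.06	1.06e-02	0.86	0.77	0.97
M01125	Isoleucine	16	0.73	0.29	1.11e-02	2.08	1.18	3.67
M16818	X-04495	11	0.35	0.14	1.32e-02	1.42	1.08	1.87
M35159	Cysteine-glutathione disulfide	9	-0.19	0.08	1.45e-02	0.82	0.71	0.96
M18477	Glycodeoxycholate	7	-0.11	0.05	1.53e-02	0.90	0.82	0.98
M33138	X-11793	11	0.30	0.13	1.67e-02	1.35	1.06	1.73
M33782	X-10346	14	0.08	0.04	1.81e-02	1.09	1.01	1.17
M12768	X-03088	16	-0.30	0.13	2.43e-02	0.74	0.57	0.96
M33203	X-11858	15	0.06	0.03	2.92e-02	1.06	1.01	1.12
M35186	1-arachidonoylglycerophosphoethanolamine	17	-0.32	0.15	3.05e-02	0.72	0.54	0.97
M33192	X-11847	11	0.10	0.05	3.31e-02	1.11	1.01	1.22
M11438	Phosphate	4	-0.84	0.40	3.40e-02	0.43	0.20	0.94
M35464	X-13671	14	-0.38	0.18	3.45e-02	0.68	0.48	0.97
M34530	X-12847	10	0.13	0.06	4.22e-02	1.14	1.00	1.30
M33973	Epiandrosterone sulfate	3	0.20	0.10	4.31e-02	1.22	1.01	1.49
M01114	Deoxycholate	17	0.11	0.05	4.41e-02	1.11	1.00	1.24
M33968	5-Dodecenoate (12:1n7)	11	-0.18	0.09	4.95e-02	0.83	0.70	1.00
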