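snp_id	chrom	pos	phenotype	beta_lipolysis	p_lipolysis	ref_lipolysis	alt_lipolysis	freq_lipolysis	beta_trait	p_trait	ref_trait	alt_trait	freq_trait
rs967605	1	23399932	spontaneous	0.07	7.78E-03	T	C	0.14	-0.02	3.68E-13	C	T	0.83
rs10923724	1	119546842	spontaneous	0.05	8.33E-03	T	C	0.40	-0.01	1.14E-12	C	T	0.57
rs919433	2	198166565	spontaneous	-0.04	2.67E-02	A	G	0.62	0.01	1.36E-11	G	A	0.36
rs4515655	9	128616073	spontaneous	-0.04	4.37E-02	C	T	0.38	-0.01	1.01E-09	C	T	0.40
rs17105272	14	77529783	spontaneous	-0.04	4.15E-02	T	C	0.67	0.01	2.22E-09	C	T	0.32
rs967605	1	23399932	stimulated	-0.06	1.63E-03	T	C	0.14	-0.02	3.68E-13	C	T	0.83
rs2850969	4	102183594	stimulated	0.04	2.81E-02	C	T	0.85	-0.01	2.16E-09	C	T	0.86
rs4502319	9	101481205	stimulated	-0.03	2.76E-02	A	G	0.29	-0.01	2.59E-12	G	A	0.75
rs10118701	9	103061366	stimulated	0.04	1.02E-02	G	A	0.66	-0.01	3.46E-12	G	A	0.68
rs4515655	9	128616073	stimulated	0.03	4.34E-02	C	T	0.38	-0.01	1.01E-09	C	T	0.40
rs3781099	10	27318776	stimulated	0.05	4.67E-02	T	C	0.92	0.02	8.07E-11	C	T	0.08
rs1558236	12	111780998	stimulated	-0.09	2.09E-02	G	C	0.97	0.06	9.85E-15	G	C	0.97
rs2537847	17	65694355	stimulated	0.03	3.14E-02	G	A	0.25	-0.01	3.39E-09	G	A	0.24
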