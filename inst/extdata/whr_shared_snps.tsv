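snp_id	chrom	pos	phenotype	beta_lipolysis	p_lipolysis	ref_lipolysis	alt_lipolysis	freq_lipolysis	beta_trait	p_trait	ref_trait	alt_trait	freq_trait
rs10923724	1	119546842	spontaneous	0.05	8.33E-03	T	C	0.40	0.03	NA	C	T	0.56
rs10055995	5	137698299	spontaneous	-0.06	5.17E-04	T	C	0.42	-0.01	NA	C	T	0.58
rs10980979	9	113912553	spontaneous	0.04	1.75E-02	G	A	0.51	-0.02	NA	G	A	0.52
rs7472491	11	130271647	spontaneous	0.04	2.74E-02	G	A	0.35	0.01	NA	G	A	0.36
rs10878367	12	66436097	spontaneous	-0.05	2.04E-02	A	T	0.73	0.02	NA	T	A	0.30
rs12325187	16	3364997	spontaneous	-0.04	2.27E-02	G	C	0.69	0.01	NA	G	C	0.73
rs4794033	17	47358481	spontaneous	-0.06	1.68E-02	A	G	0.88	-0.02	NA	G	A	0.10
rs1328757	20	56135199	spontaneous	0.05	4.73E-03	T	C	0.56	0.01	NA	C	T	0.47
rs10055995	5	137698299	stimulated	0.03	1.03E-02	T	C	0.418	-0.01	NA	C	T	0.58
rs1319817	6	41702227	stimulated	-0.05	4.30E-02	C	G	0.933	0.03	NA	G	C	0.06
rs10878367	12	66436097	stimulated	0.03	2.64E-02	A	T	0.727	0.02	NA	T	A	0.30
rs7974861	13	51221618	stimulated	0.05	1.04E-02	A	C	0.153	0.04	NA	C	A	0.89
rs146182298	14	52531408	stimulated	-0.09	2.47E-02	T	C	0.969	0.03	NA	C	T	0.04
rs11074934	16	10979440	stimulated	0.04	1.15E-02	T	C	0.737	0.01	NA	C	T	0.27
rs4794033	17	47358481	stimulated	0.05	2.08E-02	A	G	0.883	-0.02	NA	G	A	0.10
rs9909443	17	73308346	stimulated	-0.04	3.85E-03	T	C	0.780	-0.01	NA	C	T	0.23
rs4646342	17	17493272	stimulated	-0.03	3.91E-02	A	G	0.550	-0.02	NA	G	A	0.45
rs8126001	20	62711459	stimulated	0.03	2.98E-02	T	C	0.516	-0.02	NA	C	T	0.49
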