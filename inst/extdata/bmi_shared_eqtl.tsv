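snp_id	phenotype	gene	tissue	p_nominal	high_allele	low_allele	fdr_pass	detected_in_hascs
rs967605	spontaneous	ZNF436	SAT	0.0000086	C	T	TRUE	TRUE
rs967605	spontaneous	ZNF436-AS1	SAT	0.000018	C	T	TRUE	FALSE
rs10923724	spontaneous	WARS2	SAT	1.70E-46	C	T	TRUE	TRUE
rs10923724	spontaneous	TBX15	SAT	0.0000097	T	C	TRUE	TRUE
rs919433	spontaneous	ANKRD44	SAT	7.30E-13	G	A	TRUE	FALSE
rs4515655	spontaneous	PBX3	SAT	3.10E-17	T	C	TRUE	FALSE
rs17105272	spontaneous	RP11-7F17.3	SAT	4.20E-09	T	C	TRUE	FALSE
rs967605	stimulated	ZNF436	SAT	8.60E-06	C	T	TRUE	TRUE
rs967605	stimulated	ZNF436-AS1	SAT	1.80E-05	C	T	TRUE	FALSE
rs2850969	stimulated	FLJ20021	SAT	1.90E-11	T	C	TRUE	TRUE
rs4502319	stimulated	ANKS6	SAT	0.000065	G	A	TRUE	FALSE
rs10118701	stimulated	INVS	SAT	1.70E-13	G	A	TRUE	TRUE
rs10118701	stimulated	STX17	SAT	1.50E-07	G	A	TRUE	TRUE
rs4515655	stimulated	PBX3	SAT	3.10E-17	T	C	TRUE	FALSE
rs3781099	stimulated	MASTL	SAT	4.20E-11	C	T	TRUE	FALSE
rs3781099	stimulated	LINC00202-1	SAT	0.0000022	T	C	TRUE	FALSE
rs1558236	stimulated	ALDH2	SAT	0.0000018	G	C	TRUE	TRUE
rs2537847	stimulated	RP11-855A2.1	SAT	0.000071	A	G	TRUE	FALSE
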