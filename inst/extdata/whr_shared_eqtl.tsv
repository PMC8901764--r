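snp_id	phenotype	gene	tissue	p_nominal	high_allele	low_allele	fdr_pass	detected_in_hascs
rs10923724	spontaneous	WARS2	SAT	NA	C	T	TRUE	TRUE
rs10923724	spontaneous	TBX15	SAT	NA	T	C	TRUE	TRUE
rs10055995	spontaneous	REEP2	SAT	NA	C	T	TRUE	FALSE
rs10055995	spontaneous	KDM3B	SAT	NA	T	C	TRUE	FALSE
rs10980979	spontaneous	LPAR1	SAT	NA	A	G	TRUE	FALSE
rs7472491	spontaneous	ADAMTS8	VAT	NA	G	A	TRUE	FALSE
rs10878367	spontaneous	LLPH-AS1	SAT	NA	A	T	TRUE	FALSE
rs12325187	spontaneous	TIGD7	SAT	NA	G	C	TRUE	FALSE
rs12325187	spontaneous	ZNF263	SAT	NA	G	C	TRUE	TRUE
rs12325187	spontaneous	LINC00921	SAT	NA	C	G	TRUE	FALSE
rs12325187	spontaneous	ZNF200	SAT	NA	G	C	TRUE	FALSE
rs12325187	spontaneous	MTCO1P28	VAT	NA	G	C	TRUE	FALSE
rs4794033	spontaneous	ZNF652	SAT	NA	A	G	TRUE	FALSE
rs1328757	spontaneous	PCK1	SAT	NA	T	C	TRUE	TRUE
rs10055995	stimulated	REEP2	SAT	NA	C	T	TRUE	FALSE
rs10055995	stimulated	KDM3B	SAT	NA	T	C	TRUE	FALSE
rs1319817	stimulated	TFEB	SAT	NA	G	C	TRUE	FALSE
rs10878367	stimulated	LLPH-AS1	SAT	NA	A	T	TRUE	FALSE
rs7974861	stimulated	EBPL	SAT	NA	A	C	TRUE	TRUE
rs146182298	stimulated	NID2	VAT	NA	C	T	TRUE	TRUE
rs11074934	stimulated	CIITA	SAT	NA	T	C	TRUE	FALSE
rs4794033	stimulated	ZNF652	SAT	NA	A	G	TRUE	FALSE
rs9909443	stimulated	GGA3	SAT	NA	T	C	TRUE	TRUE
rs9909443	stimulated	MRPS7	SAT	NA	C	T	TRUE	TRUE
rs9909443	stimulated	NUP85	SAT	NA	T	C	TRUE	TRUE
rs9909443	stimulated	MIF4GD	SAT	NA	C	T	TRUE	FALSE
rs9909443	stimulated	GRB2	SAT	NA	T	C	TRUE	TRUE
rs4646342	stimulated	PEMT	SAT	NA	G	A	TRUE	TRUE
rs8126001	stimulated	OPRL1	SAT	NA	T	C	TRUE	FALSE
rs8126001	stimulated	RGS19	SAT	NA	T	C	TRUE	FALSE
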