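read_id	sample_id	chrom_a	strand_a	start_a	end_a	chrom_b	strand_b	start_b	end_b	donor_gene_sym	donor_exon	acceptor_gene_sym	acceptor_exon	row	section
row01_r01	HBR	chr3	+	999976	1000000	chr3	+	1501759	1501783	IQCJ	4/5	SCHIP1	2/8	1	long_range
row01_r02	HBR	chr3	+	999976	1000000	chr3	+	1501759	1501783	IQCJ	4/5	SCHIP1	2/8	1	long_range
row02_r01	N3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r02	T2	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r03	T2	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r04	T2	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r05	T2	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r06	T2	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r07	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r08	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r09	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r10	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r11	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r12	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r13	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r14	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r15	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r16	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r17	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r18	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r19	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r20	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row02_r21	T3	chr21	-	1000000	1000024	chr21	-	-2062487	-2062463	TMPRSS2	1/14	ERG	4/11	2	long_range
row03_r01	UHR	chr17	+	999976	1000000	chr17	+	925064	925088	RPS6KB1	4/15	TMEM49	12/12	3	scrambled
row03_r02	UHR	chr17	+	999976	1000000	chr17	+	925064	925088	RPS6KB1	4/15	TMEM49	12/12	3	scrambled
row04_r01	UHR	chr12	-	1000000	1000024	chr12	-	1157193	1157217	GCN1L1	2/58	MSI1	12/15	4	scrambled
row04_r02	UHR	chr12	-	1000000	1000024	chr12	-	1157193	1157217	GCN1L1	2/58	MSI1	12/15	4	scrambled
row05_r01	UHR	chr13	+	999976	1000000	chr13	-	1185373	1185397	GAS6	12/15	RASA3	23/24	5	inversion
row05_r02	UHR	chr13	+	999976	1000000	chr13	-	1185373	1185397	GAS6	12/15	RASA3	23/24	5	inversion
row05_r03	UHR	chr13	+	999976	1000000	chr13	-	1185373	1185397	GAS6	12/15	RASA3	23/24	5	inversion
row05_r04	UHR	chr13	+	999976	1000000	chr13	-	1185373	1185397	GAS6	12/15	RASA3	23/24	5	inversion
row05_r05	UHR	chr13	+	999976	1000000	chr13	-	1185373	1185397	GAS6	12/15	RASA3	23/24	5	inversion
row05_r06	UHR	chr13	+	999976	1000000	chr13	-	1185373	1185397	GAS6	12/15	RASA3	23/24	5	inversion
row05_r07	UHR	chr13	+	999976	1000000	chr13	-	1185373	1185397	GAS6	12/15	RASA3	23/24	5	inversion
row06_r01	UHR	chr2	-	1000000	1000024	chr2	+	1320033	1320057	TGOLN2	3/4	USP39	11/13	6	inversion
row06_r02	UHR	chr2	-	1000000	1000024	chr2	+	1320033	1320057	TGOLN2	3/4	USP39	11/13	6	inversion
row07_r01	UHR	chr20	+	999976	1000000	chr20	-	2172837	2172861	ARFGEF2	1/39	SULF2	3/21	7	inversion
row07_r02	UHR	chr20	+	999976	1000000	chr20	-	2172837	2172861	ARFGEF2	1/39	SULF2	3/21	7	inversion
row07_r03	UHR	chr20	+	999976	1000000	chr20	-	2172837	2172861	ARFGEF2	1/39	SULF2	3/21	7	inversion
row07_r04	UHR	chr20	+	999976	1000000	chr20	-	2172837	2172861	ARFGEF2	1/39	SULF2	3/21	7	inversion
row08_r01	UHR	chr16	-	1000000	1000024	chr16	+	12193286	12193310	LITAF	1/4	DECR2	2/9	8	inversion
row08_r02	UHR	chr16	-	1000000	1000024	chr16	+	12193286	12193310	LITAF	1/4	DECR2	2/9	8	inversion
row09_r01	N1	chr2	-	1000000	1000024	chr2	+	90944295	90944319	REV1	3/23	CPSF3	10/18	9	inversion
row09_r02	N1	chr2	-	1000000	1000024	chr2	+	90944295	90944319	REV1	3/23	CPSF3	10/18	9	inversion
row10_r01	UHR	chr20	+	999976	1000000	chr17	+	2e+06	2000024	BCAS4	1/6	BCAS3	23/24	10	translocation
row10_r02	UHR	chr20	+	999976	1000000	chr17	+	2e+06	2000024	BCAS4	1/6	BCAS3	23/24	10	translocation
row10_r03	UHR	chr20	+	999976	1000000	chr17	+	2e+06	2000024	BCAS4	1/6	BCAS3	23/24	10	translocation
row10_r04	UHR	chr20	+	999976	1000000	chr17	+	2e+06	2000024	BCAS4	1/6	BCAS3	23/24	10	translocation
row11_r01	UHR	chr22	+	999976	1000000	chr9	+	2e+06	2000024	BCR	14/23	ABL1	2/11	11	translocation
row11_r02	UHR	chr22	+	999976	1000000	chr9	+	2e+06	2000024	BCR	14/23	ABL1	2/11	11	translocation
row11_r03	UHR	chr22	+	999976	1000000	chr9	+	2e+06	2000024	BCR	14/23	ABL1	2/11	11	translocation
row12_r01	N1	chr1	+	999976	1000000	chr12	-	1999976	2e+06	CAMTA1	3/23	SPPL3	3/11	12	translocation
row12_r02	N1	chr1	+	999976	1000000	chr12	-	1999976	2e+06	CAMTA1	3/23	SPPL3	3/11	12	translocation
row13_r01	UHR	chr14	+	999976	1000000	chr12	+	2e+06	2000024	DYNC1H1	24/78	EIF4B	8/15	13	translocation
row13_r02	UHR	chr14	+	999976	1000000	chr12	+	2e+06	2000024	DYNC1H1	24/78	EIF4B	8/15	13	translocation
row14_r01	T3	chr16	-	1000000	1000024	chr15	+	2e+06	2000024	MBTPS1	22/23	SERF2	3/3	14	translocation
row14_r02	T3	chr16	-	1000000	1000024	chr15	+	2e+06	2000024	MBTPS1	22/23	SERF2	3/3	14	translocation
row15_r01	N2	chrX	+	999976	1000000	chr5	-	1999976	2e+06	OGT	6/22	RBM22	4/11	15	translocation
row15_r02	N2	chrX	+	999976	1000000	chr5	-	1999976	2e+06	OGT	6/22	RBM22	4/11	15	translocation
row16_r01	N1	chr9	-	1000000	1000024	chr17	-	1999976	2e+06	ROR2	1/9	USP36	2/20	16	translocation
row16_r02	N1	chr9	-	1000000	1000024	chr17	-	1999976	2e+06	ROR2	1/9	USP36	2/20	16	translocation
row17_r01	T3	chr4	-	1000000	1000024	chr6	-	1999976	2e+06	SEC31A	1/27	C6orf62	2/5	17	translocation
row17_r02	T3	chr4	-	1000000	1000024	chr6	-	1999976	2e+06	SEC31A	1/27	C6orf62	2/5	17	translocation
row18_r01	UHR	chr14	-	1000000	1000024	chr8	-	1999976	2e+06	TIMM9	3/6	PRKDC	26/86	18	translocation
row18_r02	UHR	chr14	-	1000000	1000024	chr8	-	1999976	2e+06	TIMM9	3/6	PRKDC	26/86	18	translocation
row19_r01	N1	chr22	+	999976	1000000	chr19	+	2e+06	2000024	ZDHHC8	4/11	UBL5	3/5	19	translocation
row19_r02	N1	chr22	+	999976	1000000	chr19	+	2e+06	2000024	ZDHHC8	4/11	UBL5	3/5	19	translocation
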