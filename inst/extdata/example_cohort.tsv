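Tumor_Sample_Barcode	Hugo_Symbol	Chromosome	Start_Position	Reference_Allele	Tumor_Seq_Allele2	Variant_Classification	t_alt_count	t_depth	RNA_alt_count	RNA_ref_count	NMD_score	purity	ncn	tcn
s0004	driver01	chr1	1000040	C	T	Silent	42	121	6	29	.	0.5892	2	2
s0005	driver01	chr1	1000050	C	T	Nonsense_Mutation	25	168	16	35	0.4487	0.3152	2	3
s0007	driver01	chr1	1000070	C	T	Silent	6	61	32	69	.	0.4197	2	2
s0008	driver01	chr1	1000080	C	T	Missense_Mutation	19	87	13	9	.	0.7080	2	4
s0010	driver01	chr1	1000100	C	T	Missense_Mutation	6	32	5	6	.	0.7519	2	2
s0012	driver01	chr1	1000120	C	T	Silent	37	104	14	50	.	0.5577	2	2
s0005	driver02	chr2	2000050	C	T	Missense_Mutation	11	126	6	6	.	0.3152	2	2
s0006	driver02	chr2	2000060	C	T	Nonsense_Mutation	20	89	2	4	0.9546	0.6051	2	2
s0007	driver02	chr2	2000070	C	T	Nonsense_Mutation	19	87	1	0	0.9881	0.4197	2	2
s0008	driver02	chr2	2000080	C	T	Splice_Site	29	103	10	16	.	0.7080	2	3
s0009	driver02	chr2	2000090	C	T	Missense_Mutation	28	49	17	1	.	0.6866	2	1
s0010	driver02	chr2	2000100	C	T	Silent	13	88	1	10	.	0.7519	2	2
s0011	driver02	chr2	2000110	C	T	Missense_Mutation	13	44	6	2	.	0.6037	2	2
s0004	gene0001	chr3	3000040	C	T	Nonsense_Mutation	30	84	4	13	0.5290	0.5892	2	2
s0003	gene0002	chr4	4000030	C	T	Nonsense_Mutation	4	70	1	1	0.3095	0.7475	2	2
s0001	gene0003	chr5	5000010	C	T	Missense_Mutation	7	62	2	22	.	0.5103	2	3
s0006	gene0003	chr5	5000060	C	T	Silent	19	124	0	8	.	0.6051	2	1
s0012	gene0003	chr5	5000120	C	T	Silent	27	65	9	11	.	0.5577	2	1
s0003	gene0005	chr7	7000030	C	T	Silent	24	118	5	6	.	0.7475	2	4
s0005	gene0005	chr7	7000050	C	T	Silent	3	98	0	3	.	0.3152	2	2
s0009	gene0005	chr7	7000090	C	T	Silent	59	102	3	1	.	0.6866	2	1
s0012	gene0005	chr7	7000120	C	T	Nonsense_Mutation	15	92	0	14	0.7018	0.5577	2	3
s0003	gene0006	chr8	8000030	C	T	Nonsense_Mutation	10	46	3	70	0.7892	0.7475	2	3
s0005	gene0006	chr8	8000050	C	T	Missense_Mutation	17	134	2	21	.	0.3152	2	1
s0011	gene0008	chr10	10000110	C	T	Missense_Mutation	25	82	23	24	.	0.6037	2	2
s0012	gene0008	chr10	10000120	C	T	Nonsense_Mutation	7	65	1	6	0.2484	0.5577	2	4
s0005	gene0009	chr11	11000050	C	T	Silent	10	37	0	0	.	0.3152	2	1
s0009	gene0009	chr11	11000090	C	T	Missense_Mutation	17	70	0	0	.	0.6866	2	2
s0010	gene0009	chr11	11000100	C	T	Missense_Mutation	10	40	0	0	.	0.7519	2	3
s0003	gene0010	chr12	12000030	C	T	Missense_Mutation	30	77	0	0	.	0.7475	2	2
s0005	gene0010	chr12	12000050	C	T	Silent	13	83	0	0	.	0.3152	2	2
s0006	gene0010	chr12	12000060	C	T	Missense_Mutation	17	48	0	0	.	0.6051	2	1
s0008	gene0010	chr12	12000080	C	T	Nonsense_Mutation	15	62	0	0	0.9900	0.7080	2	3
s0001	gene0011	chr13	13000010	C	T	Missense_Mutation	25	83	5	36	.	0.5103	2	2
s0002	gene0011	chr13	13000020	C	T	Silent	69	81	86	11	.	0.9149	2	1
s0001	gene0012	chr14	14000010	C	T	Missense_Mutation	15	74	0	10	.	0.5103	2	2
s0004	gene0012	chr14	14000040	C	T	Silent	15	39	7	20	.	0.5892	2	1
s0007	gene0012	chr14	14000070	C	T	Missense_Mutation	12	65	6	17	.	0.4197	2	2
s0008	gene0012	chr14	14000080	C	T	Silent	18	67	1	1	.	0.7080	2	2
s0009	gene0013	chr15	15000090	C	T	Silent	27	92	3	5	.	0.6866	2	2
s0012	gene0013	chr15	15000120	C	T	Missense_Mutation	22	88	0	1	.	0.5577	2	2
s0003	gene0014	chr16	16000030	C	T	Missense_Mutation	21	61	67	91	.	0.7475	2	2
s0007	gene0014	chr16	16000070	C	T	Missense_Mutation	18	74	21	228	.	0.4197	2	2
s0008	gene0015	chr17	17000080	C	T	Missense_Mutation	4	90	0	5	.	0.7080	2	3
s0009	gene0015	chr17	17000090	C	T	Silent	19	79	10	25	.	0.6866	2	3
s0003	gene0016	chr18	18000030	C	T	Missense_Mutation	71	129	35	22	.	0.7475	2	1
s0004	gene0016	chr18	18000040	C	T	Missense_Mutation	12	50	44	64	.	0.5892	2	2
s0011	gene0016	chr18	18000110	C	T	Silent	24	47	67	67	.	0.6037	2	1
s0012	gene0016	chr18	18000120	C	T	Missense_Mutation	10	95	29	122	.	0.5577	2	4
s0002	gene0018	chr20	20000020	C	T	Silent	24	75	1	7	.	0.9149	2	2
s0003	gene0018	chr20	20000030	C	T	Missense_Mutation	15	63	1	34	.	0.7475	2	3
s0007	gene0018	chr20	20000070	C	T	Silent	20	74	24	24	.	0.4197	2	1
s0011	gene0018	chr20	20000110	C	T	Missense_Mutation	4	46	1	31	.	0.6037	2	2
s0012	gene0018	chr20	20000120	C	T	Nonsense_Mutation	7	64	8	22	0.9316	0.5577	2	2
s0007	gene0019	chr21	21000070	C	T	Missense_Mutation	1	47	2	25	.	0.4197	2	2
s0008	gene0019	chr21	21000080	C	T	Missense_Mutation	41	79	12	17	.	0.7080	2	1
s0012	gene0019	chr21	21000120	C	T	Missense_Mutation	26	100	7	19	.	0.5577	2	2
s0012	gene0020	chr22	22000120	C	T	Missense_Mutation	14	58	0	19	.	0.5577	2	3
s0002	gene0021	chr1	23000020	C	T	Missense_Mutation	18	55	2	10	.	0.9149	2	3
s0006	gene0021	chr1	23000060	C	T	Missense_Mutation	19	69	2	1	.	0.6051	2	4
s0007	gene0021	chr1	23000070	C	T	Missense_Mutation	23	111	0	2	.	0.4197	2	3
s0008	gene0021	chr1	23000080	C	T	Nonsense_Mutation	30	109	1	4	0.2781	0.7080	2	4
s0011	gene0021	chr1	23000110	C	T	Silent	11	89	3	6	.	0.6037	2	4
s0004	gene0022	chr2	24000040	C	T	Silent	12	63	15	41	.	0.5892	2	1
s0005	gene0022	chr2	24000050	C	T	Silent	2	101	12	100	.	0.3152	2	3
s0010	gene0022	chr2	24000100	C	T	Silent	11	76	18	81	.	0.7519	2	2
s0011	gene0022	chr2	24000110	C	T	Missense_Mutation	7	44	74	249	.	0.6037	2	3
s0004	gene0023	chr3	25000040	C	T	Silent	30	92	73	80	.	0.5892	2	2
s0008	gene0023	chr3	25000080	C	T	Silent	31	80	71	59	.	0.7080	2	2
s0010	gene0023	chr3	25000100	C	T	Silent	27	44	70	122	.	0.7519	2	1
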