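contig_id	gene_id	gene_index	lineage	bit_score	e_value
omz_virus_01	omz_virus_01_1	1	Sulfolobus spindle-shaped virus 1	131.2	3.2e-40
omz_virus_01	omz_virus_01_2	2	Haloarcula hispanica icosahedral virus SH1	96.4	9.57e-30
omz_virus_01	omz_virus_01_3	3	Halorubrum pleomorphic virus 1	88.1	3.0100000000000004e-27
omz_virus_01	omz_virus_01_4	4	Methanobacterium phage psiM2	210.5	4.3e-64
omz_virus_01	omz_virus_01_5	5	Pyrococcus abyssi virus 1	79.3	1.3399999999999999e-24
omz_virus_01	omz_virus_01_6	6		0	NA
omz_virus_01	omz_virus_01_7	7		0	NA
omz_virus_01	omz_virus_01_8	8		0	NA
omz_phage_01	omz_phage_01_1	1	Prochlorococcus phage P-SSM2	250.1	5.159999999999999e-76
omz_phage_01	omz_phage_01_2	2	Synechococcus phage S-PM2	180.2	5.679999999999999e-55
omz_phage_01	omz_phage_01_3	3	Pelagibacter phage HTVC010P	93	1.01e-28
omz_phage_01	omz_phage_01_4	4	Escherichia phage T4	85.5	1.83e-26
omz_phage_01	omz_phage_01_5	5		0	NA
omz_phage_01	omz_phage_01_6	6		0	NA
omz_phage_01	omz_phage_01_7	7		0	NA
omz_sparse_01	omz_sparse_01_1	1	Sulfolobus islandicus rod-shaped virus 2	100.3	6.41e-31
omz_sparse_01	omz_sparse_01_2	2	Halovirus HF2	77.8	3.7999999999999995e-24
omz_sparse_01	omz_sparse_01_3	3		0	NA
omz_sparse_01	omz_sparse_01_4	4		0	NA
omz_sparse_01	omz_sparse_01_5	5		0	NA
omz_sparse_01	omz_sparse_01_6	6		0	NA
omz_sparse_01	omz_sparse_01_7	7		0	NA
omz_sparse_01	omz_sparse_01_8	8		0	NA
omz_sparse_01	omz_sparse_01_9	9		0	NA
omz_sparse_01	omz_sparse_01_10	10		0	NA
omz_sparse_01	omz_sparse_01_11	11		0	NA
omz_sparse_01	omz_sparse_01_12	12		0	NA
omz_sparse_01	omz_sparse_01_13	13		0	NA
omz_sparse_01	omz_sparse_01_14	14		0	NA
omz_sparse_01	omz_sparse_01_15	15		0	NA
omz_sparse_01	omz_sparse_01_16	16		0	NA
omz_sparse_01	omz_sparse_01_17	17		0	NA
omz_sparse_01	omz_sparse_01_18	18		0	NA
omz_sparse_01	omz_sparse_01_19	19		0	NA
omz_sparse_01	omz_sparse_01_20	20		0	NA
omz_sparse_01	omz_sparse_01_21	21		0	NA
omz_sparse_01	omz_sparse_01_22	22		0	NA
omz_sparse_01	omz_sparse_01_23	23		0	NA
omz_sparse_01	omz_sparse_01_24	24		0	NA
omz_sparse_01	omz_sparse_01_25	25		0	NA
omz_sparse_01	omz_sparse_01_26	26		0	NA
omz_sparse_01	omz_sparse_01_27	27		0	NA
omz_sparse_01	omz_sparse_01_28	28		0	NA
omz_sparse_01	omz_sparse_01_29	29		0	NA
omz_sparse_01	omz_sparse_01_30	30		0	NA
omz_sparse_01	omz_sparse_01_31	31		0	NA
omz_sparse_01	omz_sparse_01_32	32		0	NA
omz_sparse_01	omz_sparse_01_33	33		0	NA
omz_sparse_01	omz_sparse_01_34	34		0	NA
omz_sparse_01	omz_sparse_01_35	35		0	NA
omz_sparse_01	omz_sparse_01_36	36		0	NA
omz_sparse_01	omz_sparse_01_37	37		0	NA
omz_sparse_01	omz_sparse_01_38	38		0	NA
omz_sparse_01	omz_sparse_01_39	39		0	NA
omz_sparse_01	omz_sparse_01_40	40		0	NA
omz_sparse_01	omz_sparse_01_41	41		0	NA
omz_sparse_01	omz_sparse_01_42	42		0	NA
omz_sparse_01	omz_sparse_01_43	43		0	NA
omz_sparse_01	omz_sparse_01_44	44		0	NA
omz_sparse_01	omz_sparse_01_45	45		0	NA
omz_sparse_01	omz_sparse_01_46	46		0	NA
omz_sparse_01	omz_sparse_01_47	47		0	NA
omz_sparse_01	omz_sparse_01_48	48		0	NA
omz_sparse_01	omz_sparse_01_49	49		0	NA
omz_sparse_01	omz_sparse_01_50	50		0	NA
omz_sparse_01	omz_sparse_01_51	51		0	NA
omz_sparse_01	omz_sparse_01_52	52		0	NA
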