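name	sequence	role
BC1_01	GTAGGGCG	BC1
BC1_02	TCATTTGT	BC1
BC1_03	CGACCCTC	BC1
BC1_04	TAGCATAC	BC1
BC1_05	CTGTGCCT	BC1
BC1_06	ACGGTAGG	BC1
BC1_07	GGGACGTA	BC1
BC1_08	CATGACAG	BC1
BC1_09	TTTAGTCA	BC1
BC1_10	GCTCTGGC	BC1
BC1_11	AGTTCATT	BC1
BC1_12	GACTAGAT	BC1
BC1_13	ATCCGACC	BC1
BC1_14	CCCATCGA	BC1
BC1_15	TGCGCTTG	BC1
BC1_16	GGAATACC	BC1
BC1_17	ACAGCGAT	BC1
BC1_18	CTATATTG	BC1
BC1_19	TAACGCGA	BC1
BC1_20	CGGCTTCA	BC1
BC1_21	TCGTCCAG	BC1
BC1_22	GTGGAATT	BC1
BC1_23	AAGAGGGC	BC1
BC1_24	TGTGTCCT	BC1
BC1_25	CCTACTAC	BC1
BC1_26	ATTCAGTA	BC1
BC1_27	GATTGAGG	BC1
BC1_28	AGCTTGCG	BC1
BC1_29	GCCCCAAA	BC1
BC1_30	TTCAACTC	BC1
BC1_31	CACGGTGT	BC1
BC1_32	TTAACAGG	BC1
BC1_33	CAAGTGTA	BC1
BC1_34	AGATGTAC	BC1
BC1_35	GCACACCT	BC1
BC1_36	ATGCCTGT	BC1
BC1_37	GAGTTCTC	BC1
BC1_38	TGGGGAAA	BC1
BC1_39	CCGAAGCG	BC1
BC1_40	GTTGCCGA	BC1
BC1_41	AATATTTG	BC1
BC1_42	CGTCGGAT	BC1
BC1_43	TCTTAACC	BC1
BC1_44	CTCTCGGC	BC1
BC1_45	TACCTATT	BC1
BC1_46	GGCAGCAG	BC1
BC1_47	ACCGATCA	BC1
BC1_48	CCAAGATT	BC1
BC2_01	AAATTGGC	BC2
BC2_02	AAACCTTG	BC2
BC2_03	AAAGGCCT	BC2
BC2_04	GGTTGTAT	BC2
BC2_05	GGTACCGG	BC2
BC2_06	GGTGTATC	BC2
BC2_07	GGTCAGCA	BC2
BC2_08	TTCCTCAC	BC2
BC2_09	TTCGATGA	BC2
BC2_10	TTCAGGTT	BC2
BC2_11	TTCTCACG	BC2
BC2_12	CCGGCGAG	BC2
BC2_13	CCGCGAGT	BC2
BC2_14	CCGTACTA	BC2
BC2_15	CCGATTCC	BC2
BC2_16	AGGGCAGA	BC2
BC2_17	AGGCGGAC	BC2
BC2_18	AGGTATCG	BC2
BC2_19	AGGATCTT	BC2
BC2_20	GACCTTGT	BC2
BC2_21	GACGACAG	BC2
BC2_22	GACAGACC	BC2
BC2_23	GACTCGTA	BC2
BC2_24	TCTTGCGC	BC2
BC2_25	TCTACTAA	BC2
BC2_26	TCTGTGCT	BC2
BC2_27	TCTCAATG	BC2
BC2_28	CTAAAGGG	BC2
BC2_29	CTATTAAT	BC2
BC2_30	CTACCCCA	BC2
BC2_31	CTAGGTTC	BC2
BC2_32	ATTTGATA	BC2
BC2_33	ATTACGCC	BC2
BC2_34	ATTGTTAG	BC2
BC2_35	ATTCACGT	BC2
BC2_36	GCAAATTT	BC2
BC2_37	GCATTCCG	BC2
BC2_38	GCACCAAC	BC2
BC2_39	GCAGGGGA	BC2
BC2_40	TAGGCCTC	BC2
BC2_41	TAGCGTCA	BC2
BC2_42	TAGTAGAT	BC2
BC2_43	TAGATAGG	BC2
BC2_44	CGCCTGTG	BC2
BC2_45	CGCGAACT	BC2
BC2_46	CGCAGCAA	BC2
BC2_47	CGCTCTGC	BC2
BC2_48	ACCCTACA	BC2
BC3_01	ATGCAGGG	BC3
BC3_02	ACTGATTT	BC3
BC3_03	AGCTACCC	BC3
BC3_04	AATTGGTA	BC3
BC3_05	ATCGGACG	BC3
BC3_06	ACACGCAT	BC3
BC3_07	AGGAGTGC	BC3
BC3_08	AACCTTCA	BC3
BC3_09	ATTATCTG	BC3
BC3_10	ACGTTAGT	BC3
BC3_11	AGAGTGAC	BC3
BC3_12	AAGGCCGA	BC3
BC3_13	ATATCTAG	BC3
BC3_14	ACCACGCT	BC3
BC3_15	AGTCCATC	BC3
BC3_16	CTTGTTAA	BC3
BC3_17	CACTTCGG	BC3
BC3_18	CGAATATT	BC3
BC3_19	CCGCTGCC	BC3
BC3_20	CTACCCTA	BC3
BC3_21	CAGACTCG	BC3
BC3_22	CGTTCGAT	BC3
BC3_23	CCCGCAGC	BC3
BC3_24	CTGTAACA	BC3
BC3_25	CAAGAGTG	BC3
BC3_26	CGCCATGT	BC3
BC3_27	CCTAACAC	BC3
BC3_28	CTCAGGGA	BC3
BC3_29	CATCGAAG	BC3
BC3_30	CGGGGCCT	BC3
BC3_31	CCATGTTC	BC3
BC3_32	GCCTCCAA	BC3
BC3_33	GGTGCTGG	BC3
BC3_34	GAGCCGTT	BC3
BC3_35	GTAACACC	BC3
BC3_36	GCGATTTA	BC3
BC3_37	GGACTCCG	BC3
BC3_38	GACGTAAT	BC3
BC3_39	GTTTTGGC	BC3
BC3_40	GCAGGGCA	BC3
BC3_41	GGGTGATG	BC3
BC3_42	GATAGCGT	BC3
BC3_43	GTCCGTAC	BC3
BC3_44	GCTCAAGA	BC3
BC3_45	GGCAAGAG	BC3
BC3_46	GAATATCT	BC3
BC3_47	GTGGACTC	BC3
BC3_48	TGGCGGAA	BC3
H3K4me1	ACGTC	antibody
H3K4me3	AGTCG	antibody
H3K27ac	ATCGT	antibody
H3K27me3	CCCCA	antibody
H3K36me3	CATGC	antibody
IgG	CTGAG	antibody
RT01	CGATT	rt
RT02	GGGGA	rt
RT03	GTACC	rt
RT04	GACTG	rt
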