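mirna_id	sequence	length_nt	mfe_kcal_mol	mfei
miR_1	TTGTTTTTCCTATTCCACCAAT	22	-41.8	1.2
miR_2	TTTAAGAATTTCAGTTATGC	20	-411	2
miR_3	TAACTGAATATTCTTAAAG	19	-411	2
miR_4	GCTCTCTATATTTCTGTCATC	21	-48	1
miR_5	TGCTGCTAGTTCATGGATACC	21	-83.7	1.1
miR_6	CATGTGCCCCTCTTCCCCATC	21	-55.3	0.8
miR_7	GGCAAGTTGGCCTTGGCTATA	21	-69.1	1
miR_8	AAGTAGAGTGCAGCCAAGGAT	21	-63.5	1
miR_9	TCGTCCTGAGACCACATGAGA	21	-61.4	0.9
miR_10	GGGCAATGGCTTCTTTGGCAGT	22	-59.6	0.8
miR_11	AACCTTGGTGACTAATTAGATACC	24	-83.3	2.2
miR_12	TTCTTTCAAACAGGCCCTGAG	21	-48.1	1.1
miR_13	AATAGAATTCTAGATTAGAAGATC	24	-37.9	0.8
miR_14	AGAGACCGAGACACGTCATGACGT	24	-34.1	1
miR_15	CCCGTGCGACCAAAATAAATTATT	24	-54.5	0.8
miR_16	TATGATTTCCTTTGCTTCCTC	21	-72.6	1.3
miR_17	TCTTCTCTCTATTGTCACCTT	21	-520	0.9
miR_18	CATTTGTTTCTTTCTCTCCTTATA	24	-50.7	1.2
miR_19	AATGGAGCATAGATATTGAATATA	24	-82.5	1.5
miR_20	TTAGATTTTAAAATTTGGGAC	21	-17	1.3
miR_21	TGGATGAGACGCTCATTTGAG	21	-45.5	1.1
miR_22	GACACGGACACATCATTTAAGAGA	24	-30.8	1
miR_23	AAACGAATTTTCAACGTGGACTGT	24	-35.2	0.9
miR_24	ACAAGAGGCAGAAAGTAGAGTG	22	-57.9	1
miR_25	CATCAAGATTGTATACAACTCT	22	-93.6	1.5
miR_26	CAAATGAGTATTCCATCTACA	21	-45.5	1.1
miR_27	ATGAAAATCCAGAACTCATAACTC	24	-36.4	0.9
miR_28	CTAATCAAGGAAATCACAGTAG	22	-33.5	0.8
miR_29	CGTTCCTGCATGGGGGCACCA	21	-87.2	1.1
miR_30	GCCGAGAATTGAGATCCATAACTC	24	-52.5	0.8
miR_31	AAAATAAATTATTATGGTCGTCGT	24	-54.5	0.8
miR_32	GGTTTGTGCGTGAATCTGACG	21	-44.88	1.1
miR_33	TAACTGAATATTCTTAAAGCCT	22	-411	2
miR_34	AAGGGTTTCTATCAGAGTTTA	21	-48.6	0.8
miR_35	TGTAAAACCCTGAATCCAAACCAT	24	-79.8	1
miR_36	CAATGAGGGCATGTTGTAGGC	21	-54.5	1
miR_37	GGGCATATCTTCTTTGGCACA	21	-56.6	0.9
miR_38	ACCAGAGTTTCCATTTTAACATAT	24	-71	1.7
miR_39	TAAGATGAAAACAAGGATACACT	23	-66.4	0.9
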