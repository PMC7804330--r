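mirna_id	family	sequence	length_nt	arm
pvu-miR1510a	MIR1510	TGGAGGATTAGGTAAAACAAC	21	3p
pvu-miR1515a	MIR1515	TCATTTTGCGTGCAATGATCTG	22	5p
pvu-miR156d	MIR156	GCTCACTTCTCTTTCTGTCAACT	23	3p
pvu-miR156c	MIR156	GCTTACTCTCTATCTGTCACC	21	3p
pvu-miR156i	MIR156	TGACAGAAGAGAGTGAGCAC	20	5p
pvu-miR156s	MIR156	TGACAGAAGAGAGTGAGCACT	21	5p
pvu-miR156w	MIR156	TTGACAGAAGAGAGAGAGCAC	21	5p
pvu-miR156ab	MIR156	TTGACAGAAGATAGAGAGCAC	21	5p
pvu-miR159a.1	MIR159	TTTGGATTGAAGGGAGCTCTA	21	3p
pvu-miR319b	MIR159	TGAGCTTTCTTCAGTCCACTC	21	5p
pvu-miR319q	MIR159	TGGACTGAAGGGAGCTCCTTC	21	3p
pvu-miR319a	MIR159	TTGGACTGAAGGGAGCTCCC	20	3p
pvu-miR159a	MIR159	GAGCTCCTTGAAGTCCAATT	20	5p
pvu-miR160a	MIR160	TGCCTGGCTCCCTGTATGCCA	21	5p
pvu-miR162b	MIR162_1	GGAGGCAGCGGTTCATCGATC	21	5p
pvu-miR162	MIR162_1	TCGATAAACCTCTGCATCCAG	21	3p
pvu-miR164a	MIR164	TGGAGAAGCAGGGCACGTGCA	21	5p
pvu-miR166g	MIR166	CTCGGACCAGGCTTCATTCC	20	3p
pvu-miR166d	MIR166	GAATGTTGTCTGGCTCGAGGA	21	5p
pvu-miR166i	MIR166	GGAATGTCGTCTGGTTCGAGA	21	5p
pvu-miR166e	MIR166	GGAATGTTGGCTGGCTCGAGG	21	5p
pvu-miR166c	MIR166	GGAATGTTGTCTGGCTCGAGG	21	5p
pvu-miR166m	MIR166	GTCGGACCAGGCTTCATTCCC	21	5p
pvu-miR166b	MIR166	TCGGACCAGGCTTCATTCCCA	21	3p
pvu-miR166a	MIR166	TCGGACCAGGCTTCATTCCCC	21	3p
pvu-miR166j	MIR166	TCGGACCAGGCTTCATTCCCG	21	3p
pvu-miR166k	MIR166	TCTCGGACCAGGCTTCATTC	20	3p
pvu-miR166h	MIR166	TCTCGGACCAGGCTTCATTCC	21	3p
pvu-miR167g	MIR167_1	AGATCATGTGGCAGTTTCACC	21	3p
pvu-miR167b	MIR167_1	TGAAGCTGCCAGCATGATCT	20	5p
pvu-miR167d	MIR167_1	TGAAGCTGCCAGCATGATCTGG	22	5p
pvu-miR167j	MIR167_1	TGAAGCTGCCAGCATGATCTTA	22	5p
pvu-miR168b	MIR168	CCCGCCTTGCATCAACTGAAT	21	3p
pvu-miR168c	MIR168	CCCGCCTTGCATCAACTGAATT	22	3p
pvu-miR168a	MIR168	TCGCTTGGTGCAGGTCGGGAA	21	5p
pvu-miR169k	MIR169_2	CAGCCAAGAATGACTTGCCGG	21	5p
pvu-miR169c	MIR169_2	CAGCCAAGGATGACTTGCCGG	21	5p
pvu-miR169g	MIR169_2	CAGCCAAGGATGACTTGCCGGA	22	5p
pvu-miR169b	MIR169_2	CGGCAAGTGGTTCTTGGCTAC	21	3p
pvu-miR169a	MIR169_2	GGCAAGTTGTTCTTGGCTAC	20	3p
pvu-miR171a	MIR171_1	TATTGGCCTGGTTCACTCAGA	21	5p
pvu-miR171m	MIR171_1	TTGAGCCGCGTCAATATCTCA	21	3p
pvu-miR2118	MIR2118	TTGCCGATTCCACCCATTCCTA	22	3p
pvu-miR319r	MIR319	GAGTTCTTTGCAGCCCAAAGC	21	5p
pvu-miR319e	MIR319	TTTGGACTGAAGGGAGCTCCT	21	3p
pvu-miR390b	MIR390	AAGCTCAGGAGGGATAGCACC	21	5p
pvu-miR390a	MIR390	AAGCTCAGGAGGGATAGCGCC	21	5p
pvu-miR390c	MIR390	CGCTATCCATCCTGAGTTTC	20	3p
pvu-miR393e	MIR393	TCCAAAGGGATCGCATTGATCC	22	5p
pvu-miR394c	MIR394	TTGGCATTCTGTCCACCT	18	5p
pvu-miR394b	MIR394	TTGGCATTCTGTCCACCTCC	20	5p
pvu-miR394a	MIR394	TTGGCATTCTGTCCACCTCCT	21	5p
pvu-miR395e	MIR395	AGTTCCTCTGAGCACTTCACA	21	5p
pvu-miR395a	MIR395	CTGAAGTGTTTGGGGGAGCTC	21	3p
pvu-miR395g	MIR395	TGAAGTGTTTGGGGGAACTTT	21	3p
pvu-miR396b	MIR396	GCTCAAGAAAGCTGTGGGAGA	21	3p
pvu-miR396i	MIR396	GTTCAATAAAGCTGTGGGAAG	21	3p
pvu-miR396a	MIR396	TTCCACAGCTTTCTTGAACTG	21	5p
pvu-miR396e	MIR396	TTCCACAGCTTTCTTGAACTT	21	5p
pvu-miR398b	MIR398	TTTGTGTTCTCAGGTCACCCC	21	3p
pvu-miR399f	MIR399	GGGCAACTTCTCCTTTGGCAGT	22	5p
pvu-miR399i	MIR399	TGCCAAAGGAGAGCTGCCCTG	21	3p
pvu-miR399a	MIR399	TGCCAAAGGAGAGTTGCCCTG	21	3p
pvu-miR403a	MIR403	TTAGATTCACGCACAAACTTG	21	3p
pvu-miR408c	MIR408	ATGCACTGCCTCTTCCCTGGC	21	3p
pvu-miR482	MIR482	GGAATGGGCTGATTGGGAAGC	21	5p
pvu-miR482b	MIR482	TCTTCCCTACACCTCCCATACC	22	3p
pvu-miR482a	MIR482	TTCCCAATTCCGCCCATTCCTA	22	3p
pvu-MIR530a	MIR530	TGCATTTGCACCTGCGCTTTG	21	5p
pvu-miR399m	MIR530	AGGGCACCTCTCTCCTGGCAG	21	5p
pvu-miR156g	MIR530	GCTCTCTCTTCCTCTGTCATC	21	3p
pvu-miR1514a	MIR530	TTCATTTTGAAAATAGGCATTG	22	5p
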