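mirna	sequence	length	abundance_seed	abundance_leaf	position	conservation
zma-miR01	AAAAAGCCAGAACGATTTATGA	22	15	NA	Intron	NA
zma-miR02a	AAGCAAGGATAATGGAGGGGA	21	9	NA	Intron	NA
zma-miR02b	AAGCAAGGATAATGGAGGGGA	21	9	NA	Intron	NA
zma-miR03	ACCGATCGGGAGAACCGGAGA	21	NA	37	Overlap	NA
zma-miR04	ACGGTGTTGTGTCAGGGGGGT	21	6	NA	Intergenic	NA
zma-miR05	AGAACCGGAGAGCTAGAGGG	20	NA	5	Overlap	NA
zma-miR06	AGAGGAGATTGAAGGGGCTAG	21	6	NA	Intergenic	NA
zma-miR07	AGAGGATCTATGGTGGAGGAA	21	5	NA	Intron	NA
zma-miR08	AGATATGGTAGAGGGGCCTAA	21	7	NA	Intergenic	O. sativa
zma-miR09	AGCTATGAACGTCTGGATGCA	21	NA	5	Intergenic	NA
zma-miR10	AGTGTTTGGTTAGATGGAATAG	22	NA	26	Intergenic	NA
zma-miR11	ATACTAGGAGTGAAGGGATCA	21	8	NA	Intron	NA
zma-miR12	ATATATGTGGGTTGGGATTAAT	22	5	NA	Intron	NA
zma-miR13	ATCACAGGAGGATTGGAGGAG	21	9	NA	Intron	NA
zma-miR14a	ATGGAGGGGATTGAGGGGCTA	21	NA	9	Intergenic	NA
zma-miR14b	ATGGAGGGGATTGAGGGGCTA	21	NA	9	Intergenic	NA
zma-miR14c	ATGGAGGGGATTGAGGGGCTA	21	NA	9	Intergenic	NA
zma-miR15	ATGGTGCATTGACTTGGTCAA	21	NA	5	Intron	NA
zma-miR16	ATTGTAGTGGATTGAGAGGGA	21	8	NA	Intergenic	NA
zma-miR17	ATTTTTGAAGGAAGGAAAGC	20	9	NA	Overlap	S. bicolor
zma-miR18a	CAAAGAGAATTGAGGGGGCTA	21	10	7	Intergenic	NA
zma-miR18b	CAAAGAGAATTGAGGGGGCTA	21	NA	7	Intergenic	NA
zma-miR18c	CAAAGAGAATTGAGGGGGCTA	21	NA	7	Intergenic	NA
zma-miR18d	CAAAGAGAATTGAGGGGGCTA	21	10	7	Intergenic	NA
zma-miR19	CCAACAGGATATTGGGTATTTC	22	169	NA	Intergenic	O. sativa
zma-miR20	CGCAGCGTTGATGAGCCAGCCG	22	57	7	Intergenic	S. bicolor
zma-miR21	CGGCTCACCAGCGCTGCACTC	21	6	NA	Intergenic	NA
zma-miR22a	CTGAAAAGTGTGGCGCGGTGT	21	NA	9	Intergenic	NA
zma-miR22b	CTGAAAAGTGTGGCGCGGTGT	21	NA	9	Intergenic	NA
zma-miR23a	GAGACAGACAACATATGTAGAA	22	NA	26	Intron	NA
zma-miR23b	GAGACAGACAACATATGTAGAA	22	5	NA	Intron	NA
zma-miR24	GAGCGCAGCGTTGATGAGCCAG	22	5	NA	Intergenic	S. bicolor
zma-miR25	GGAGGAGATGGGAGTGGCTAA	21	12	NA	Intergenic	S. bicolor
zma-miR26a	GTCACAGAAGTTGGGATGCAA	21	5	NA	Intron	S. bicolor
zma-miR26b	GTCACAGAAGTTGGGATGTAA	21	NA	13	Intron	S. bicolor
zma-miR27a	GTGATCACGGGAGATTGGAGA	21	NA	7	Intergenic	NA
zma-miR27b	GTGATCACGGGAGATTGGAGA	21	48	NA	Intergenic	NA
zma-miR28	TAGAGAGGATTAAAGTGGCTA	21	NA	5	Intergenic	NA
zma-miR29	TAGCTCTTCCTGTTTGGATAT	21	5	NA	Intergenic	S. bicolor
zma-miR30	TAGGGATCTATGGAGAGGAA	20	5	NA	Intergenic	NA
zma-miR31	TCAACACACGTGGATTGCGGT	21	NA	6	Intron	NA
zma-miR32	TCACAAGGGGATTGAAGAGGA	21	5	NA	Intron	NA
zma-miR33	TCACTTTGGGATCACAGATAA	21	10	NA	Intron	NA
zma-miR34	TCAGAAAATATGAACTTGAGA	21	NA	19	Intron	NA
zma-miR35	TCATAAGGGGATAAACAACGC	21	NA	5	Intron	NA
zma-miR36	TCGGGGTTAGAGGGGATTGAG	21	6	NA	Intergenic	O. sativa
zma-miR37	TGAAAAGCTAGAACGATTTAC	21	5	NA	Intron	NA
zma-miR38a	TGAAGAGAATTGAGGGGGCTA	21	17	NA	Intergenic	NA
zma-miR38b	TGAAGAGAATTGAGGGGGCTA	21	17	NA	Intron	NA
zma-miR39	TGGACAGGGAAATGAAGGGGA	21	16	NA	Intergenic	NA
zma-miR40	TGGAGGGGATTGAGGGGCATA	21	NA	8	Intergenic	NA
zma-miR41	TTAGATGGGATACATGAGAGG	21	NA	5	Intergenic	NA
zma-miR42	TTAGTAGTTTTAGTTCTTTGC	21	5	NA	Intergenic	A. thaliana
zma-miR43	TTTAGTGATCAGCTGGAGGTT	21	NA	5	Intron	S. bicolor
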