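Name	Chromosome	Position	Variation type	F1	F2	R
C1	1	8431159	A/T	GAAGGTGACCAAGTTCATGCTGCTAAAGAGTTTAACTGGTTAATCTTAGATA	GAAGGTCGGAGTCAACGGATTGCTAAAGAGTTTAACTGGTTAATCTTAGATT	CTAATGGACCTACAAATCATGAACTCCAA
C2	1	14051095	T/A	GAAGGTGACCAAGTTCATGCTTCAATGTCCTGATCTTGTTGTCATCTT	GAAGGTCGGAGTCAACGGATTTCAATGTCCTGATCTTGTTGTCATCTA	TTTCATATAACATGGACCTTGGATGGTTATA
C3	2	589455	T/C	GAAGGTGACCAAGTTCATGCTTATATTAGGTTTAAATGCTACTTTGGTCCT	GAAGGTCGGAGTCAACGGATTTATTAGGTTTAAATGCTACTTTGGTCCC	GGACCAAAGTGAACCAAAACCAAAAGTATA
C4	2	15914116	G/A	GAAGGTGACCAAGTTCATGCTAAATTTTGTTAAACTCGTTTCCGTTCATAG	GAAGGTCGGAGTCAACGGATTGAAATTTTGTTAAACTCGTTTCCGTTCATAA	TAACCTCAAAGTTCTAAACTCAAAATTATTCTTTA
C5	3	3421007	A/T	GAAGGTGACCAAGTTCATGCTGTGGCCTCACCCACTATTTTTCAAA	GAAGGTCGGAGTCAACGGATTGTGGCCTCACCCACTATTTTTCAAT	GTATTGTGTATTTTGTGTTATCTGATTGTTATATTT
C6	3	28241399	T/C	GAAGGTGACCAAGTTCATGCTTAGTAGTCTTAGTGATCTCGAAGGAAT	GAAGGTCGGAGTCAACGGATTGTAGTCTTAGTGATCTCGAAGGAAC	TTCGAGATCACTATGACTGCCATGATAT
C7	4	5104280	T/C	GAAGGTGACCAAGTTCATGCTGAGACATGTGGCATTTTTTTAGTTT	GAAGGTCGGAGTCAACGGATTGAGACATGTGGCATTTTTTTAGTTC	CCATGTCATTACAACGAAAGTCC
C8	4	20784251	C/A	GAAGGTGACCAAGTTCATGCTCCGGACCTGTTCACTTCATCAC	GAAGGTCGGAGTCAACGGATTGCCGGACCTGTTCACTTCATCAA	GATTCAGCTACGCCGCCGTCAA
C9	5	1706273	C/T	GAAGGTGACCAAGTTCATGCTGAGAAGATCAATAGAAACCCC	GAAGGTCGGAGTCAACGGATTGAGAAGATCAATAGAAACCCT	CCTGTGCCTGATGCTCATGTCC
C10	5	27139793	T/C	GAAGGTGACCAAGTTCATGCTGTTCCCACTACCACTAGGCCAAT	GAAGGTCGGAGTCAACGGATTTTCCCACTACCACTAGGCCAAC	AGTGTATTAAATTAAAGAAGCATTTAAACCATCAT
C11	6	1594854	A/G	GAAGGTGACCAAGTTCATGCTGAGCTTAACTTGCTATGCACCTAGA	GAAGGTCGGAGTCAACGGATTAGCTTAACTTGCTATGCACCTAGG	CCATTAAGAGGGAGTCTCACATCTAAAA
C12	6	5974943	G/A	GAAGGTGACCAAGTTCATGCTGTACTATTGTCAATTATACATGCTGAGG	GAAGGTCGGAGTCAACGGATTGTACTATTGTCAATTATACATGCTGAGA	GACCGACTCTCTCAACCATATCCAT
C13	7	11605465	T/C	GAAGGTGACCAAGTTCATGCTTCGATGGTGTTCGTGATGAGACT	GAAGGTCGGAGTCAACGGATTCGATGGTGTTCGTGATGAGACC	CATATTGCCCATGAGGTGAGGCTT
C14	7	23829758	T/C	GAAGGTGACCAAGTTCATGCTGGATAGATGGGGATCAGCT	GAAGGTCGGAGTCAACGGATTGGATAGATGGGGATCAGCC	AAAAACTTGCATTGCGAACTCC
C15	8	20000834	A/G	GAAGGTGACCAAGTTCATGCTCCACTCTACCCACCCGAGGA	GAAGGTCGGAGTCAACGGATTCACTCTACCCACCCGAGGG	GTAATGTTGTTGCTCATTCTTCGGCTTAAA
C16	8	22529614	T/C	GAAGGTGACCAAGTTCATGCTGTGGACTGTTAATGTACCCATGTGAT	GAAGGTCGGAGTCAACGGATTTGGACTGTTAATGTACCCATGTGAC	TAGAGCATCATATCAATCACAGGCCTAA
C17	9	10095406	T/C	GAAGGTGACCAAGTTCATGCTTTGCAAATTCCTCCCAAATTGAGTAGT	GAAGGTCGGAGTCAACGGATTGCAAATTCCTCCCAAATTGAGTAGC	CTAGGGTACTACTCATGATTCTATCTCTT
C18	9	18607803	A/G	GAAGGTGACCAAGTTCATGCTTTGCATACTATCGATTGTAAGAAGGAAAAA	GAAGGTCGGAGTCAACGGATTGCATACTATCGATTGTAAGAAGGAAAAG	CAACGCTCTTGCCAGTAATTCTTTGATT
C19	10	2343761	C/A	GAAGGTGACCAAGTTCATGCTTCGTTGATGGGTGACGGTAAATTTC	GAAGGTCGGAGTCAACGGATTTATCGTTGATGGGTGACGGTAAATTTA	GACCAAACACACATATTGTTAGATGATATAATAA
C20	10	4261004	T/C	GAAGGTGACCAAGTTCATGCTCAGCTTATGTTTCCTGTTCTAGT	GAAGGTCGGAGTCAACGGATTCAGCTTATGTTTCCTGTTCTAGC	AGAGAACTCAAGATCACCTCCCAAGT
C21	11	14865743	G/T	GAAGGTGACCAAGTTCATGCTATAGTTTGATCTAGAATTGTTTGTAATAATTTG	GAAGGTCGGAGTCAACGGATTGATAGTTTGATCTAGAAATTGTTTGTAATATTT	ACAAACATTAGAAACTTTTACAACTTACACACTT
C22	11	15431610	G/A	GAAGGTGACCAAGTTCATGCTATTCTAATACTTTGAGAATACAAACTCTTTTTG	GAAGGTCGGAGTCAACGGATTATTCTAATACTTTGAGAATACAAACTCTTTTTA	GCCAATGAAATAGAAATAATATATCACATGTAAAAT
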