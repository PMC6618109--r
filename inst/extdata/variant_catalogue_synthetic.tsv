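name	sequence	clade	accession
C3	CGTTTCGGGAAGATCTGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTA	C	NA
C3a	CGTTTCGGGAAGATCCGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTA	C	NA
C3ab	CGGTTCGGGAAGATCTGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCAGGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTA	C	NA
C3c	CGTTTCGGAAAGATCTGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTA	C	NA
C3aq	CGTTTCGGGAAGATCTGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTTAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTCCAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTA	C	NA
C3am	CGTTTCGGGAAGATCTGAGTTTGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGATTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTA	C	NA
C3gulf	CGTTTCGGGAAGATCTGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATAGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTA	C	NA
C3d	CGTTTCGGGAAGATCTGAGTATGTAAGCTTGAAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTTACCAGTTCAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTA	C	NA
C3i	CGTTTCGGGAAGATCTGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACACGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTAGCACGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAGTAACCTA	C	NA
C115c	CGTTTCGGGAAGATCTGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCAGTTCCGGATTAACCAGTTTAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATTACCTA	C	NA
C115b	CGTTTCGGGAAGATCTGAGTATGTAAGCTTGTAAACGTTCGACATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGGACAATACCCTCGACGTCTCTGAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATTGCACTGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTA	C	NA
C15	CGTTTCGGGAAGATCTGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTAATTCACTAAATCCTAAGTCGGCTGTTTGGAGCTGGGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGGACAATACCCTCGAGGTCTGTTAATCTTCAGCTACCCTCGCACGACCTGCATCCGGTGACCATTGCAATGTATGGGGTTCTCGCAACGCGATCTCAAGGTTGAATAACCTA	C	NA
C15x	CGTTTCGGGAAGATCTGAGTATGTAAGCTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTAATTCACTAAATCCTAAGTCGGCTGTTTGGAGCTGGGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGCACAATAACCTCGAGGTCTGTTAATCTTCAGCTACCCTCGCACGACCTGCATCCGGTGACCATTGCAATGTATGGGGTTCTCGCAACGCGATCTCAAGGTTGAATAACCTA	C	NA
D1	AACAGGCTTCCGGTTATAGTTTGGATCACCCCCCGCAGTCTGAGACAGAAGGTATCGGATAGCCATGCAAATTAATCTGGTCCAGCACTCGAAAGCAATGCTCACGTTGAGAAGGTCCGTGATAGAGACAGCGCCTCCTGTAAATACATTTTTTCTCGACGCTTTAAAAGCATGCGGGGTAACCAAGGTGGAACCTAGCGCTCCCCTGCATCCTCGGTAATTGGCCGGTTGTGCTCGACGATCAGCTTATATAGTAATAT	D	NA
D4	AACAGGCTTCCGGTTATAGTTTGGATCACCCCCCGCAGTCTGAGAGAGAAGGTATCGGATAGCCATGCAAATTAATCTGGTCCAGCACTCGAAAGCAATGCTCACGTTGAGAAGGTCCGTGATAGAGACAGCGCCTCCTGTAAATACATTTTTTCTCGACGCTTTAAAAGCATGCGGGGTAACCAAGGTGGAACCTAGCGCTCCCCTGCATCCTCGGTAATTGGCCGGTTGTGCTCGACGATCAGCTTATATAGTATTAT	D	NA
A1	GTAGAAAACGGTTTTATTGAATCCGGCAGTGTTGACAAACCGTATTAATCTCCAACTTTAGCACGTTGAAATATTCACCTAATCGCAAGAATTGAAATTTCAAAACACCGAAGCTCCAATAATTTGGCGAAGACGATATTAGGGTTTTAATGAAGCTCGATTAGCGGTGGTTAGCACGCGGTGCTCCGAGACATGGCACGTCTGACATGACTGAAGTAGGGTAAGACCTGAAACAGTGTCGTACACGTCCTTTTATCACT	A	NA
B1	CGCGTGAATGTAAATATGGTCCCTCGGGCAATGGAAGACGTGAAGTTATGTTAGTTGAGTAGCCGAAACTAATCGTTTACATGAGCGTGTGCCCACTGGAGAATGCCACCAGAACCATCCTCACCCCGACAATCTAGTTACTCCCAATCGGTATGTGGATTCTCGTGAATTTATGACTATCTAGATAGGCCGATATACTCCCGGTTATGATTCCTCTGGGTTAAGAGACAATTTGGTGGGTATCGGGGACAGCAGTGTTT	B	NA
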