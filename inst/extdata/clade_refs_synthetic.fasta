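>A
GAATTGCAGAACTCCGTGAACCGTAGAAAACGGTTTTATTGAATCCGGCAGTGTTGAAAAACCGTATTAATCTCCAACTTTAGCACGTTGAAATATTCACCTAATCGCAAGAATTGAAATTTCAAAACACGGAAGCTCCAATAATTTGGCGAAGACGATATTAGGGTTTTAATGAAGCTCGATTAGCGGTGGTTAGCACGCGGTGCTCCGAGACATGGCACGTCTGACATGACTGAAGTAGGGTAAGACCTGAAACAGTGTCGTACACGTCCTTTTATCACTGCATGAAGTCAGACAAGTGAACCCG
>B
GAATTGCAGAACTCCGTGAACCCGCGTGAATGTAAATATGGTCCCTCGGGCAATGGAAGACGTGAAGTTATGTTAGTTGTGTAGCCGAAACTAATCGTTTACATGAGCGTGTGCCCACTGGAGAATGCCACCAGAACCATCCTCACCCCGACAATCTAGTTACTCCCAATCGGTATGTGGATTCTCGTGAATTTATGACTATCTAGATAGGCCGATATACTCCCGGTCATGATTCCTCTGGGTTAAGAGACAATTTGGTGGGTATCGGGGACAGCAGTGTTTGCATGAAGTCAGACAAGTGAACCCG
>C
GAATTGCAGAACTCCGTGAACCCGTTTCGGGAAGATCTGAGTATGTAAGGTTGTAAACGTTCGCCATATAATTTTAAGGTCATCTAGTTATTTCACTAAATCCTGAGTCGTCTGTTTGGAGCTGAGCTCTATTTCCCCCAAAACCTGTTCCGGATTAACCAGTTCAACAGGGACAATACCCTCGACGTCTGTTAATCTTCAGCTACACTCGCACGACCTGCATCCGGTGACCATTGCAATGTATGGGGGTCTCGCAACGACATCTCAAGGTTGAATAACCTAGCATGAAGTCAGACAAGTGAACCCG
>D
GAATTGCAGAACTCCGTGAACCAACAGGCTTCCGGTTATAGTTTGGATCACCCCCCGCAGTCTGAGACAGAAGGTATCGGATAGCCATGCAAATTAATCTGGTCCAGCACTCGAAAGCAATGCTCACGTTGAGAAGGTCCGTGATAGAGACAGCGCCGCCTGTAAATACATTTTTTCTCGACGCTTTAAAAGCATGCGGGGTAACCAAGGTGGAACCTAGCGCTCCCCTGCATCCTCGGTAATTGGCCGCTTGTGCTCGACGATCAGCTTATATAGTAATATGCATGAAGTCAGACAAGTGAACCCG
>E
GAATTGCAGAACTCCGTGAACCCCGTGTCTTTCACGATGCTCAGGGCCGTTAGCACCAGCTTGGATTATCTTACGTATTGTAGTTGTCTATTCGTTTAGTGGCTATGCGAATGGAACCCATGACTCCTTTTCAGAGGTTGGACAACAAGTGCGATTGGGGCCTGAGAGACCGACCTACTCAATTTCGCTGCGCGTGCCCTGTGCACACCGTCAAGCTCGGTCACCCTGAACTTGGACCCCTTTTTCGACCTCTGTAATAGACCTGGCTGTTGCACTTTCGCTGCATGAAGTCAGACAAGTGAACCCG
>F
GAATTGCAGAACTCCGTGAACCGACGCAGCGGCCAAGACAGGTGAGATGACATTGGGCCAATATCGCCGCGAAGAATTTGCCGGGCCAGTCCCAGCGGTGTTTTACATTCGGGTATTAAGGTACCTAATACTCTCCGCTTCGCTGGTTGCCGGGCGATTCCGAGACTCCAACGAGTCGTTCTGCGACATTCCCGCTCTACTACCAGCTTGCAAAGGCTCCGGAATCCGACTTACTCCTGTCATTCGAAGACTGCCGCGCTCCACGACAGCGGAGTAATGTGTGCATGAAGTCAGACAAGTGAACCCG
>G
GAATTGCAGAACTCCGTGAACCCTGAGTTATTACCGCTGATAAATTCACCGTTATTTAACCGGCCCGACGCGATATCATCAGGACCGTAGACGGGAGACTGTGAATTCCACACCATCGCCAGCGACGCTGTTCCTCCGTGGACACCAGAAGTTGCTCTGAGCTTGTCCCAAAACACTGAAGGTAAATATCATCGCTGATGGGAGCGTTGCCAGACATGTGGCTCTCTATAGGGAAATGCCGAATCATCTCCATCATTCCGATCTGTATGAACATAGTTGCAAGCATGAAGTCAGACAAGTGAACCCG
>H
GAATTGCAGAACTCCGTGAACCCGGGGTACAGCCCAACCACCTGAAGAGCTGGTATAATACCCAGATGGTATTTACATCCTAAGCTCCTGATCCCCTTCCACTGAGCATACGGTCACGCCAAGCAATGGTTATGGCCGTTGTCAGCAGTGCAGACCGAAGGTGTATTGGCATGAGTCCATTGTCACGCAGAATATACGATTTCGGTAGAAGTATCGGTTTATGTGGCGGGGCTGGTAGGAGAACCGATGGGGCCAATTGTGGCGCCAGCCTAATGACGAGTAGCATGAAGTCAGACAAGTGAACCCG
>I
GAATTGCAGAACTCCGTGAACCCATCCTTTAACGAGCATTACAGGTTATTATCTTTTAAATGATAACATCTGAAAAATACACCGGGCGAGTGCTAGCCTCATTCGACGATTTCCTAGTATCTTTCTCCGTATGAAAAAGGGTCCGTCGTTATTCGACCAGGGCGCAGCCTCTAGTTAGAAAAATCCTTCTGTTTTCCGATAATTGCACAACTCATCCACAAGAGGCGTAGGTCCGTTATAACATCACTTTCTAGAACTTGCTAGGGGCACAAACAGCCTGCTGCATGAAGTCAGACAAGTGAACCCG
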