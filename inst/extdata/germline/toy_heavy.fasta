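>TOYV1-1*01
ACGGTAACGAGTATAGTCGACCTGGACTGAGGAGATTACAGTTGTTGTACGTTAAGCTGAGAGTGTCTTGGCGGGTGC
>TOYV1-2*01
CAAAAAAAGGTCCCCTGGTGCGCACTTTAACCATGTACGTATCGGTTGGGTACTCGCCGGTGGTTCTGTGGGCGACTGAGA
>TOYV1-3*01
CGCGAGTATAATGAACGCTTGCTGTAGTGCGAAATTTAGCGTAGTTTGCTGCGGTCTATCCCTCGTAGCTGTCGGCCCACCGCT
>TOYV1-4*01
TTATAAGAACACAGGCTTACAGTGGACTACCCGGGGAGTTATGTTGTGGACCAATGCTGGAGACATGCGTTTACATGTAAAGCCTAGGAT
>TOYD1-1*01
TCCTTTCAGCAAATGG
>TOYD1-2*01
TTATACCGAGTCGC
>TOYD1-3*01
GATAACATAGAG
>TOYJ1-1*01
CGCTAAAAGTGGCTGTCCAAAACACCTCTCGAC
>TOYJ1-2*01
CCATTAACGTAGTGGAGTCGTCCAATGTTGTCATTA
>TOYJ1-3*01
GTATTCTTTTGGGCCCTCTAGCTGTTTAGT
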