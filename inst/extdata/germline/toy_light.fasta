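>TOYLV1-1*01
GTTGGGCTAGTCACACACTGACCCAGCATTACAGCATTCAAGTTACCAGTACTGATTGTTTGTACTCTATGAAAT
>TOYLV1-2*01
CTGACCGCGCGCAAAAGCAGCCACATGTCTACTATCACGCTCAGACACTGTGCTCACCTCAGGGATTGTCAGAGCTATCTT
>TOYLJ1-1*01
GTATGCTGGTGGTCGTTTTAGCTAAGACCGGAC
>TOYLJ1-2*01
AAGAGGCTTCCCTGGACAGAGTGTTTGGATCCTAAC
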