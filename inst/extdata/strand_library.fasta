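>0A
GCAGCGTTAATTCCCGCGCCTATCGGGAATGTAACGCAGTGGGTAATAATGACGATAGCC
GTTCGGGAAAAGCGAACGGTATCG
>0B
GCAGCGATACCGTTCGCTTTTCCCGAACGGCTATCGCAGTGGGTAATAATGAGCGAACTG
TCGGTGCTTGCGACAGTGTCGC
>0C
GCAGGCGACACTGTCGCAAGCACCGACAGTTCGCCAGTGGGTAATAATGAGCGGTTCCTT
GCGGAGTAGGCAAGGAATCCGC
>0D
GCAGGCGGATTCCTTGCCTACTCCGCAAGGAATCGCCAGTGGGTAATAATGACGTTACAT
TCCCGATAGGCGCGGGAATTAACG
>0A*
GCTGCGCATTAACGCGCTTGTCCCGCGTTAATTGCGCTCATTATTACCCACTCGCTCTCG
GCTGTTTTGCCCAGCCGAGCAGCG
>0B*
GCTGCGTTGCATTGGCGATCAAAGCCAATGCGAACGCTCATTATTACCCACTCGCAATTA
ACGCGGGACAAGCGCGTTAATGCG
>0C*
GCTGGTTGGAGAAGGCGAACAGCACGCCTTCCCAACCTCATTATTACCCACTCGTTCGCA
TTGGCTTTGATCGCCAATGCAACG
>0D*
GCTGCGCTGCTCGGCTGGGCAAAACAGCCGAGAGCGCTCATTATTACCCACTGTTGGGAA
GGCGTGCTGTTCGCCTTCTCCAAC
>1A
GCAGCGTTAATTCCCGCGCCTATCGGGAATGTAACGCAAAAGAAGAGAAAGACGATAGCC
GTTCGGGAAAAGCGAACGGTATCG
>1B
GCAGCGATACCGTTCGCTTTTCCCGAACGGCTATCGCAAAAGAAGAGAAAGAGCGAACTG
TCGGTGCTTGCGACAGTGTCGC
>1C
GCAGGCGACACTGTCGCAAGCACCGACAGTTCGCCAAAAGAAGAGAAAGAGCGGTTCCTT
GCGGAGTAGGCAAGGAATCCGC
>1D
GCAGGCGGATTCCTTGCCTACTCCGCAAGGAATCGCCAAAAGAAGAGAAAGACGTTACAT
TCCCGATAGGCGCGGGAATTAACG
>1A*
GCTGCGCATTAACGCGCTTGTCCCGCGTTAATTGCGCTCTTTCTCTTCTTTTCGCTCTCG
GCTGTTTTGCCCAGCCGAGCAGCG
>1B*
GCTGCGTTGCATTGGCGATCAAAGCCAATGCGAACGCTCTTTCTCTTCTTTTCGCAATTA
ACGCGGGACAAGCGCGTTAATGCG
>1C*
GCTGGTTGGAGAAGGCGAACAGCACGCCTTCCCAACCTCTTTCTCTTCTTTTCGTTCGCA
TTGGCTTTGATCGCCAATGCAACG
>1D*
GCTGCGCTGCTCGGCTGGGCAAAACAGCCGAGAGCGCTCTTTCTCTTCTTTTGTTGGGAA
GGCGTGCTGTTCGCCTTCTCCAAC
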