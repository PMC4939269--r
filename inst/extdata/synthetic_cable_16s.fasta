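>synthetic_cable_contig_1
AGAGTTTGATCCTGGCTCAGGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGG
ACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACT
CGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATATCCTCCGGTAGTAGTCGACCCCT
GAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACTCGTGCTAC
CGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAATAGCCGGGCCATGTAACAC
TGATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAGTTCCTGTTAGTTTTGGTT
AGGCACGGAACGCTATCGAGCGCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTA
TGTAATAAGACCTCGAGTACGTCGGGACGTTGGCTGTGATGTTTTGATGAGCGAAGTTCG
ACGTTGCCGATGTTTACCCTAAGGGAGACGACATCATCGCACGACTCGTCATTTGCATCA
TCTCCACTGCCCCGATGTCT
>synthetic_cable_contig_2
AGAGTTTGATCCTGGCTCAGGCTATGGACGGCTTCACCTGATGTGGAGCGAGGGTACTGA
TAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTACGAACAGTTCGTATTCCC
CATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGACCGGATGCAGCCCAACAGC
TTGGCCGGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACGATGCTTTGCACAAA
TTCTACCGCATTGATCGTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAAC
ATCCAGCTAGCAGCTGCAAGCTTTGCCTACGTGGAGTCTCTGTGAAATTCAGAGATACGC
AGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAGCCTCGTGCAGCCCTCACAAATTTC
CGCCATCAGTGATTCAGTATTGTTTCACCGCAGTTACCGTGAAGTGCCGCCATATACACA
GGTTCATGCTAGAGAAACTGCCACCCGGGCTTGCCAACCGGCAACGTGGCGTTGATTGAC
>synthetic_other_taxon_1
AGAGTTTGATCCTGGCTCAGCGCCACATGTTAGGTGGAGAGGAGCATATTACGGCCGCTC
CGATCGACAATACGACGCCCATCGCTTAATCTTTCCACGATACTCAGAGAGCCAACGCGT
GGTACTTGGTTGTAAACCAATGCCCGTGCGCCTGTTTAAGTCGGGACGACCTCGGATCCC
AGTTCAGGTGCTCTAATCATTGACTCGACAACAATCAGCTACGTACTGGCAGAGCGACAC
AACAACTGAGATACCAGAACGATACCTTCAATTCCTTTATGCCACATAGTCAAGGGACGG
GGCTCCCTAGATGAGTGGATTCACCTATCGGCGGTATATGTTTCGAAATCTGAGACGCAA
AGACCTGTATAAAATTCCCAGCCAGACGTCGAGTGAGAGAATAGCTTACAAGAAAATCGT
CCTATGAGCCAACTGTAATATACGTAGGAACTCTGCGAAGGGATAATAGTCCCTACGAAT
CTGAAAATGACTAACATGCGTCCGGTAGCAACGGTACTGATGGGTATAGGTCAATTTACG
ATAAAGGGGACGCCGAACAC
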