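>synthetic_reporter_orf_1773bp
ATGGAGCGGGACGACCAAGACAAAGTTAAGGGTTTAGCGAGATGGGCTTACGGTACCAGT
GTTGAAAATGTACATCCGGCAGATCCTGAAAGGGGAAATCGTCCGTTGTGTAACGCTATG
ACTCGAGCTGGCAATTACACTCTTCTGGTTGTTCGATGGGACAGAGACTTAATGGCGGAA
TGCCTAAAATTCGGGAGCGCAGTGACCTTCGAAAAAAGCTGTGTGCAACCCGCTATAAGA
ATCTTTATTGGACCCCATCCAATAATATTGCTCTTCATCCCCTTTCGAGTGGGGGGTAAC
TTCCACAGTAACATCCTACGCAACAAGGAACCTCTACAAGAGGTCAAACACGTAGAATGG
ACTAAAAGAAACAAGAGAAGGATTCGACTGTGGTGTTCGGTAGTATTATCCCATTCGTCC
GTAATGTATAACAGTGCGCGTCGTCGGTTTCGACCAAGATGGGTCAGGACACGGCGCGAG
ATTAATTATGGATCTGTTACTCAACGGCGCATCAGAACCCGCCTCCTATTCGAGCGTAAA
GTGAGAGAATATAGTCCAGCTCGAAACTGGGAGCAACTGTTTCGCCCCAATAACCGAAAT
CCCTTGTCGATTTGGCACCAGGAACCGATCTACGGGCGTTCTCTCAAGGGGGCCGTCCAA
CCGCGGATAGGCCAGCTGGTAGCTGATCGAGAACGGGTTTTAATCTTAGCGAGAAAGTTG
AGTCGGTCAGTACCAGGTCTTGATGTGGAGCTACACTATGTACTGCGGAACCCACACGGC
ATGTCAGAAAATAGGGGATTGGGTCTTAGTTTGTACGCAATTCACGAGCTTAGTTGCTTC
AACTCACTTAAGGTCCACCTCCAAGTGATTTACGGGGAGCATACGTCACCTGAACAGGGC
TTGCCGCTTCGTACGGCTCTATCAGGAGGCTTCGGATGTCAACGGGACTGCATAGAAGCT
CATGGTCCTCGAGGACACGGCGATTCAGTCCCTTTGGTTGCGCTCGAGGTAATAAAAGCA
GCAATGACCCGGCATACGGCCACATCATGGCATAATCCGTGGCGTGCAACCAATACTGTG
GGGACAGCACGACGATTGCGCTTTGCCTGGCGTAACGAATATCTGTTCAACGGATGTGGT
GGCTCCAATGTGAAGTGCTTCGTAACGTGCGCTTTCAACGTCGCCTGCGCGCTTAGTGCT
AAGCGGCTCGTGAATGTAAGAATTCGGGCCGAGGCTCGCAGGGCCATCACATCTGTATCT
TTGCATGACCCGGTTCTCATGCTCACGGAACTACAAACGCGCAGTCAGTCGAGAAGTGGG
CACATGCGGAAATTCTATTTGGATGGTCTCTTTAAAGCGACCCAACTGACCAGAGAAATA
AATGTCCTTACTATTCTAATAGGAGAAGGCAGCGGTTACGGGGGACGCCTCGTTACAAAA
ACATCTCTGACACTGCGTTCGCACATCCCAATGAGCATCAGGCGAATCAGAGTATTGGGG
GTCAGTTGCCTATCCCGCATCTGTGCCCACATTTATAGCATTGTGACATATTTTATTTGG
CCCCGAGCTTTTTTCGCCAAGGCAGAGCAATACGCGCCCTCCGTTTATGTGAGCCTTAGC
GATGCGCGGCGAATAAAGGAACAATTTGACTGTCGAGGGCCGGAGAGAGTAGGCACGCCC
CACTCCCGCGAACGCACGCTAACCTCACCAACCCTTCAATCTTGGGTCGTACTTGTCCAG
GTACTGCACTATACTAACCTCGTAGTCGCATAA
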