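>synthetic_chr
CAGAAAGTATCGCTCACAGTCTCCTACTAAGACCAACAATGTGCGGTGCTAAGGCAAACT
CCTCTGGTCCCGAGGAGGCTTCATCTTAGTTTGCCAGAACTCAATCAGAACCTTGAAACC
TGTGCAGGACCCCATATCGGCTATTTTTATATCCGCTGCCACCTTGGGCCCCCGCGTACT
AAGGCGGAGGTCACATTTGGAGTTGTGACCAGCTATAATTGGCATCTCGGACAGTCCAAC
TAACCAGGTACGACCGTGAAATGTTCTCCTCTTTTATGTACCACCTCATCCCGAAATACC
TGAGGTCAAGCGTTACGGACGCTATCTGTGAAGTTGTCTGCTACCCATCCCTCCCCCACA
TGGAGAAGGAGGAGAAAGGGAGCTTAGAAATGGGCTCATATGGATTTGCTCAAAAGCCAT
CCTTCGCCTCGAGCCGGAATATTTGCCGGTTTGCGAATAACCCTAACACAGGGGGGGGAC
AAGTTTGTACTATATGGGCGCGTCCACTTTTAATTCCGTACCTAATTTACATCTACCGTT
CTAACTGGAGCTACCGGGGGCCGCGGATTTGGGTGCGGTGCTCACTTCAGCATGCCGCAT
ACATTACACTGTTCAACGCCGGCCACTTCATCAAGAGTACCTCGGTCCAGCACTGCCTAA
GTCCTCACCGGCTGTTTAACTGTTTATTATTACGATAATGTGCGACTCGGACGATCCCTG
ATGGGAAATCTACAACGCATTATTCCTTGAAGAGCTCCATGGACGTCACAGCTTCATGGC
ACCGTTCCAGACGGAGGAAAAGTGAGACTTGAATAGTTCGAGCGGCTCCCCCATATTATA
CCTAGCTCACATTCTGTAATTGGCTCCTTCTCTAGAAGCCACTTACCTCGCATCAGGTGC
TCGGACTGGGCTCGTATATGGTGAGGCTTAGACGGTCGTATGACATCGCTATTATGTTAT
GCGGCTACGTTCTACTTATATCGAGGACGTATTGAAGGCGGAGATTGCTGCATGCCAAAT
TCGAGAATATATGATGATAAATAATGATTTCAGTTGTAATGTCTCAATTTTTACTGCCCT
TGGTCTAGTGGCGTCAAGGAAGAAGAGTACCGTTTTAGAATCTCATCCAGAGATCTCCTC
TTGTGTATGCCTACTAGGGACTTACCCTGTACTCTCGGGTATGACGCTGTATGCTATACG
GCCGTTTAACTCGCGTACACATATCGGTCAAATCCGTCGCCCAGTAATTTGCAATATACA
TCGTCATGTCGATGGATCTCAGCTGATTCTCAATGGTGCCTGCATCCGCAAACGCACAGA
ACCCCGCTGCAGTGTCGATGTACGATATTTGACTCACTCTTACGCTAGAGCCGATGCGTC
AAAAGGGATTGAAAGGTCTACTTAATTAAATTAAAATGAGTCCATTCGGGCGTCTGGCTG
TTTGACGCCGGCAAGTGAGATAAATTTTGTCGCGAGCTTTATCCAAGGCAATCGTGACAG
GGGTTACGTGTCGGCGGAATACGAATGGTCTGGTGGAGTATTCGCACGTGGCCGCCTGGC
CAGAGACCTCGGCGCTTGGTAGCGTGGACTGATCAGGCGCTCGTGCTGCCCAACGTGGCA
CCGCTCCGCTTGTCAATCTCCCCGCCCGCTTGTCGTACGTGCTGATGGTAGGAGGACGGC
AGTAGGGGATCTCCAGACGATGAGCTGACCAGGCGCCCGTGGTAAGAACGGCCAATCTCC
GGCAGTTCGCTAACCGCGGGTTGCCGCTGAAGATTACCTCAACCCCAGTAATATCCATCC
TTCGTCGCATACAGACTCCAAAAGCAAGTGGCGCAGGGGCATCTTCCAATCCTTGTTTGC
TGATCCGTCCGCTTTCTAGCTCGAAGGTGGTGTTCGCGTTATATTGTCCTGCTAAATTTC
CCCCAGTTACCAGTTTCGATACGGTTTGTACTCGAAGCTATATGGGGGCGTATATCAGAG
CATTCAAGAACCGAGTTAATAAGCACCTCTAATACTCTGCCCATTTAGCGAACGACCGGT
TCGCTCCTGAAACGCCGCCCAGAACGTGGG
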