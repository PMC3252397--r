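>Afe_1009
ATGTTCTCCTCTTTTATGTACCACCTCATCCCGAAATACCTGAGGTCAAGCGTTACGGAC
GCTATCTGTGAAGTTGTCTGCTACCCATCCCTCCCCCACATGGAGAAGGAGGAGAAAGGG
AGCTTAGAAATGGGCTCATATGGATTTGCTCAAAAGCCATCCTTCGCCTCGAGCCGGAAT
ATTTGCCGGTTTGCGAATAACCCTAACACAGGGGGGGGACAAGTTTGTACTATATGGGCG
CGTCCACTTTTAATTCCGTACCTAATTTACATCTACCGTTCTAACTGGAGCTACCGGGGG
CCGCGGATTTGGGTGCGGTGCTCACTTCAGCATGCCGCATACATTACACTGTTCAACGCC
GGCCACTTCATCAAGAGTACCTCGGTCCAGCACTGCCTAAGTCCTCACCGGCTGTTTAAC
TGTTTATTATTACGATAA
>Afe_1437
ATGCGGCTACGTTCTACTTATATCGAGGACGTATTGAAGGCGGAGATTGCTGCATGCCAA
ATTCGAGAATATATGATGATAAATAATGATTTCAGTTGTAATGTCTCAATTTTTACTGCC
CTTGGTCTAGTGGCGTCAAGGAAGAAGAGTACCGTTTTAGAATCTCATCCAGAGATCTCC
TCTTGTGTATGCCTACTAGGGACTTACCCTGTACTCTCGGGTATGACGCTGTATGCTATA
CGGCCGTTTAACTCGCGTACACATATCGGTCAAATCCGTCGCCCAGTAATTTGCAATATA
CATCGTCATGTCGATGGATCTCAGCTGATTCTCAATGGTGCCTGCATCCGCAAACGCACA
GAACCCCGCTGCAGTGTCGATGTACGATATTTGACTCACTCTTACGCTAGAGCCGATGCG
TCAAAAGGGATTGAAAGGTCTACTTAA
>Afe_2172
ATGCGACGAAGGATGGATATTACTGGGGTTGAGGTAATCTTCAGCGGCAACCCGCGGTTA
GCGAACTGCCGGAGATTGGCCGTTCTTACCACGGGCGCCTGGTCAGCTCATCGTCTGGAG
ATCCCCTACTGCCGTCCTCCTACCATCAGCACGTACGACAAGCGGGCGGGGAGATTGACA
AGCGGAGCGGTGCCACGTTGGGCAGCACGAGCGCCTGATCAGTCCACGCTACCAAGCGCC
GAGGTCTCTGGCCAGGCGGCCACGTGCGAATACTCCACCAGACCATTCGTATTCCGCCGA
CACGTAACCCCTGTCACGATTGCCTTGGATAAAGCTCGCGACAAAATTTATCTCACTTGC
CGGCGTCAAACAGCCAGACGCCCGAATGGACTCATTTTAATTTAA
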