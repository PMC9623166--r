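>G001
AGCTGCCGTGTGACTTTAAGTTTGCTATTAGCGCACGCCGGTCACAAACCTGTCGACGCGGATTCAGGCACCGGAGTAGT
TTGCGGCCGGCAAGGTGTATCCGAACCAGATCGGCACGAATCATTACTAGAGGAAACAAACCGGTATGACAGATGCGTGT
GACGATTGTGCCAGTCGTCCGGATAGTCCAATATAAGGATCCCGACCCACCGGAGAAGTAGAAAAATCCTATTAAGTGCC
ATTACACCCCTTAGTAATTTCCAACGGGAGGTCGAACGGCTGATATGTTCGTAGGTCGCC
>G002
CTTACCCCTAAGTCCGGCTGGACGGCCTTATTATATAGGTACCTGACTCGCACCCAATTCCACCGCCTTTAACAATGGGA
TGAAGCTACTGTCGTATACGGAGAATTGCGAGCCCACTAACCCGCTACAACGTTGTTTGTCTGAGGCGGGTTAGTCTCCG
TAAGTCTGCCTGCGTCAGGGATCGTGCTCCTTCAGCTCAACCACATTTAGTCGGCTCAGAGAAGTAAGGAAAATTTCGTT
CCGTAGGCACTTGTTGGAACAGATCCAGGCCGAGGTCCTGGAATTCAACAGAGGAATCGT
>G003
TCATCGTGAGGTCTCGAGACGGACGCCATATCAAAAGCTGACCGCAACGCTCATTCTCGCACTCTTGGGATCAGTCGCCC
CTTTTGGGGCGTCAGAGCGGCCACTCGAATGCTTATCCTAGATTTGGGAACGAACTACGTCTACCCAAATGCGAGGCTAT
CCTTACCCTACATCGCATAAACGCTATCCCGGCCTGCTTAGATAAAAATTGGAAACAGGTAGGGAAGGCCGGTCCCTGCA
TGACTGAACTATTAGTGAAACAGCCCGTTTTACTGAATAGGCTGTGATCCTCGAACGAGC
>G004
CGACGATTGCTAGCGGATATGCGTGCATGGGTGAGTCAAGTGTGCGATAGTAACCAGGGCACAGTCAGCACGTAATGGCG
ATTTGATACCTAGCTGAGAACGCTAGGGAAAACGTATATGCCCCGCCTTCAGTTCTTCGGTAAGGGTACTGTTAAATGTT
GACGGCGGGTGTAGTTTAGACTCAAAGTGAAGGTATGCTTTCTCGATGAGGTTGGTCACAACAACCTTAGGAATACCACT
GGAGGTCAATGTGCAATCAACTGTGACTCCTTGTTCTCGGACAAAGACTTCCTACGAGGC
>G005
AGTGACGTGATAGGCATTGCGTGGACCGGTGGGCCAAGCCTCCTTTACAAAGAATGCTGGCTGCTCCAATCTTATATAAG
GGAAAGGATGTACTTCCCAACAGTGACACCCGTGGTTTTCGGTCGGGAACCCAAACTTAGACTGCGAGCGAAATCCGTGG
GATGGTAGAAGTGTGTACTACTTCTATTAATGAGTTTCATTACACTAAGCTGGGGCAATCGTCGAGTAAAGTCGAACACC
GGCATCAGATAGTCACATGGCCAGGGACCAAGAGCGTCTATCACTTGCGAACGATTCCAT
>G006
GCTCATTATTTTTGAGGACCGTACATATTTGCTTAGAACGTGAGGAGATTTAGGATTGCAACTCTGTATGAGCATCATTT
ATGTGCCTGTGGTGTGCTTCAGTTTCCCGATTTCTGACCTGTTCATGATTGTTAGCAGTGCCGCGTTGCCCTTCGCATGA
TTTGAGGTCCGGCGTGAGACAGCATGCCCTGATCGCACTTTCCGGATCTGAATGCAAGCAATTATCCGCCCCTGCTATAG
GCATCGCATCTTTGGTCATTCATGTTCTTTAGATGCAGAGTTGGTCACACCCTTTTCCCC
>G007
TGGTGTTTATCGCAGATAGTTGCCTGAAGAGTGCGGAGATTTAGAAGACAGCAGTGCTGAGGCCAATCTTTAGGTAATGT
CCGCGGACCCTTGGCCTCTCTTACGTGGATGTCATAAGTGAGTCCCGAGCGTTAGGGCGCTCCGAGTGATTCTCACAGTC
TGACCACGATTTGGCAACTATGTTGAAGAGGCCTTTGCGAGTATAACGGGAAGTAGGCCTTATATAATACACCTAAAACC
GGAGGAAGCCTCCGCTGTACAAACATGTGGACTCCGCCGCCAGGATATTTCAACCCCCCC
>G008
GCTAATATCATCTATGGTCTTAACCGAGCAGGACTCTAGATATTCCCATGACCAACCAGTCCACGAGCCCTCTCCAAGAA
GCGCGTTTATATCTTTGAAAATAATAGGTCTCATATGACGCATCGATAACAAAAGAGCAGGCAGTCCCCTCACATGTTCG
TATGGTCGTACCCGGGTTCATTTCACTACAAAGTACACCGAAAGCTAGTCATTTAAATAGGGAGGACAGTCCTTAGCATC
ACATGCAGCGAGCGGGAGCTTCATCAACCGCGCGGTCGTTAAAATAATGAGCGAAACATC
>G009
TTGATAAACCAGGTGGATGTCACGGACGGCGTACGTACAATTACCCCTCTTCGGCAGGTTACTGGCGACTTACGCTAACA
TCCGCAACTAGTAGGGAGAAGCATGGCTTAGCTAGAACAAAATCGTAGTGGATAGAAAATAATGCCTAAGCGTATATTGT
AATTCAGGGTCATCCCATCACTAAGAAAGTGTTGGGTAGCAATGGGCTTCCAAGTTAGAGAATGATAAACACGAGTACTG
CAACTTATCCTCTAGAATGCTGTTGATTGTGTCATTACGCTTGTCAACGAGTCTAAACTA
>G010
CCCCTGAGGGCACGCCTAATGACAGGGATACATTACACTTTAATGGGCAAGCAGTAGTCAGCAACGTGAACAATGGTGGG
CGGCCGAAACTCACTGCACAGTGCGACGGACCCAACCTACGAGAATAGGTGCAGCCTTTTTGTTGTATGGTGCTAGGAAG
ACAAATGAAAGGCAAGCCGGGTACTCTCCGCATTAGACATGCAGCCCCTCGCCTGTATCAGCCGACGTTGGGCAGTGCAA
TGTAACTCGACAACGAGGTGGATCAGATAACGTGCCTCCCCTAACTAGGCATAATATGTA
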