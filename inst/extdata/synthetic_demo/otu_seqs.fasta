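>OTU001
AGCTGCGGTGTGACTTTAAGTTTGCTACTAGCGCACGCCGGTCACAAACCTGTCGACGCGGATTCAGGCACCGGAGTAGT
TTGCGGCCGGCAAGGTGTATCCGAACCAGATCGGCACGAATCATTACTAGAGGAAACAAACAGGTATGACAGAAGCGTGT
GACTATTGTGCCAGTCGTCCGGATAGTCCAATATAAGGATCCCGACCCACCGGAGAAGTAGAATAATCCTATTAAGTGCC
ATTACACCCCTTAGTAATTTCCAACGGGAGGTCGAACGGCTGATATGTTCGTAGGTCGCC
>OTU002
CTTACCCCTAAGTCCGGCTGGACGGCCTAATTATATAGGTACCTGACTCGCACCCAATTCCACTGCCTTTAACAATGGGA
TGAAGCTACTGTCGTATACGGAGAATTGCGAGCCCACTAACCCGCTACAACGTTGTTTGTCTGAGGCGGGTTAGTCTCCG
TAAGTCTGCGTGCGTCAGGGATCGTGCTCCTTCCGCTCAACCACATTTAGTCGGCTCAGAGAAGTAAGGAAAATTTCGTT
CGGTAGGCACTTGTTGGAACAGATCCAGGCCGAGGTCCTGAAATTCAACAGAGGAATCGT
>OTU003
TCATCGTGAGGTCTCGAGACGTACTCCATATCAAAAGCTGACCGCAACGCTCATTCTCGCACTCTTGGGATCAGTCGCCC
CTTTTGGGGCGTCAGAGCGGCCACTCGAATGCTTATCCTAGATTTGGGAACGAACTACGTCTACCCAAATGCGATGCTAT
CCTTACCCTACATCGCATAAACGGTATCCCGGCCTGCTTAGATAAAAATTGGAAACAGGTAGGGAAGGCGGGTCCCTGCA
TGACTGAACTATTAGTGAAACAGCCCGTTTTACTGACTAGGCTGTGATCCTCGAACGAGC
>OTU004
CGACGATTGCTAGCGGATATGCGTGCATGGGTGAGTCAAGTGTGCGATAGTACCCAGGGCACAGTCAGCACGTAATGGCG
ATTTCATACCTAGCTGAGAACGCTAGGGAAAACGTATATGCCCCGCCTTCAGTTCTTCGGTAAGGGTACTGTTAAATGTT
GACGGCGGGTGTAGTTTAGACTCAAGGTGAAGGTATGCTTTCTCGATGAGGTTGGTCACAGCAACCTTAGGAATACCACT
GGAGGTCAATGTGCAATCAACTGTGACTCCTTGTGCTCGGACACAGACTTCCTACGAGGC
>OTU005
AGTGACGTGATAGGCAGTGCGTGGACCGGTGGGCCAAGCCTCCTTTACAAAGAATGCTGGCTGCTCCCATCTTATATAAC
GGAAAGGATGTACTTCCCAACAGTGACACCCGTGGTTTTCGGTCGGGAACCCAAACTTAGACTGCGAGCGAAATCCGTGG
GATGGTAGAAGTGTGTACTACTTCTATTAATGAGTTTCATTACACTAAGCTGGGGGAATCGTCGAGTGAAGTCGAACACC
GGCACCAGATAGTCACATGGCCAGGGACCAAGAGCGTCTATCACTTGCGAACGATTCCAT
>OTU006
GCTCATTATTTTTGAGGACCGTACATATTTGCTTAGAACGTGAGGAGATTTAGGATTGCAACACTTTATGAGCATCATTT
ATGTGCCTGTGGTGTGCTTCACTTTCCCGATTTCTGACCTGTTCATGATTGTTAGCAGTGCCGCGTTGCCCCTCGCATGA
TTTGAGGTCCGGCGTGAGACAGCATGCCCTGATCGCACTTTCCGGATCTGAATGCAAGCAATTATCCGCCCCTGCTACAG
GCATCGCATCTTTGGTCATTCATGTTCTTTAGATGCAGAGTTGGTCACAACCTTTTCCCC
>OTU007
TGGTGTTTATCGCAGATACTTGCCTGAAGAGTGCGGAGATTTAGAAGACAGCAGTGCTGAGGCCAATCTTTAGGTAATGA
CCTCGGACCCTTGGCCTCTCTTACGTGGATGTCCTAAGTGAGTCCCGAGCGTTAGGGCGCTCCGAGTAATTCTCACAGTC
TGACCACGATTTGGCAACTATGTTGAAGATGCCTTTGCGAGTATAACGGGAAGTAGGCCTTATATAATACACCTAAAACC
GGAGGAAGCCTCCGCTGTACAAACATGTGGACTCCGCCGCCAGGATATTTCAACCCCCCC
>OTU008
GCTAATATCATCTATGGTCTTAACCGAGCAGGACTCTAGATATTCCCATGACCAACCAGTCCACGAGCCCTCTCCAAGTA
GCGCGTTTATATCTTTGAAAATAATAGGTCTCATATGACGCATCGATGACAAAAGAGCAGGCAGTCCCCTCACATGTTCG
TATGGTCGTACCCGGGTTCATTTTACTACAAAGTACACCGAAAGCTAGTCCTTTAAATAGGGAGGACAGTCCTTAGCATC
TCATGCAGCGAGCGGGAGCTTCATCAACCGCGCGGTCGTTAAAATAATGAGCTAAACATC
>OTU009
TTGATAAACCAAGTGGATGTCACGGACTGCGTACGTACAATTACCCCTCTTCGGCAGGTTACTGGCGACTTACGCTAACA
TCCGCAACTAGTAGGGAGAAGCATGGCTTATCTAGAACAAAATCGTAGTGGATAGAAAATAATGCCTACGCGTATATTGT
AATTCAGGGTCATCCCATCACTAAGAAAGTGTTGGGTAGCAATGGGCTTCCTAGTTAGAGAATGATAAACACGAGTACTG
CAACTTATCCTCTAGAATGCTGTTGATTGTGTCATTGCGCTTGTCAACGAGTCTAAACTA
>OTU010
CCCCTGAGGGCACGCCTAATGACAGGGAAACATTACACTTTAATGGGCAAGCAGTAGTCAGCAACGTGAACAATGGTGGG
CGGCCGAAACTCACTGCACAGTGCGACGGACCCAACCTACGATAATAGATGCAGCCTTTTTGTTGTATGGTGCTAGGAAG
ACAAATGAAAGGCAAGCCGGGTACTCTCCGCATCAGACATGCAGCCCCTCGCCTGTATCAGCCGACGTTGGGCAGTGCAA
GGTAACTCGACAACGAGGTGGATCAGATAACGTGCATCCCCTAACTAGGCATAATATGTA
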