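>TRAV1*01 type=V locus=TRA anchor=165
CCCCACCACAGGGACAGGTCGCCAAGTTTAGGCGGCCACTTCCATCGATCTACTCGATGCTCTATTAGTACGTTCGTTTGGCCAGGAGCAACGGCAAATAGCCTCGCACGGCTACCCGAATACATGCTCCCTCTTAATCTACGACAGGGAGTCGCCAGACTAAAGTGTGCTGTGAGAGGA
>TRAV2*01 type=V locus=TRA anchor=165
TCACATTGTCCTAGAACTAGGAACATACTACATACGCCTTTGTGTGTTCCGCGTAGAGAACGCACACGTCGTTTGTGGAGGGACGCAGCTACAGATGGCCCGGTAATTCGCGCCGCTCTGAGAGAAACCACAAGTTTCTGCCAACGTATTCCAGCCGCCGAGTGTTGTGCTGTGAGAGGA
>TRAV3*01 type=V locus=TRA anchor=165
TCCAAAAAATATAGTAAATTTGGGGCTTTCTCAATAGGCGGCGGGTATAGAGCACGCATCATGCCCAGGACACTACTTCTTGCCGGAGTTTATTCAATCATTGGGTACCATGATATGGACTGGGCACTTATCGCATCTAAAAAAACGTTGAACGGGAAACCTACATGTGCTGTGAGAGGA
>TRAV4*01 type=V locus=TRA anchor=165
CCGCATCCTACGCGGGGAGAACGCGATATAGTCCTATCTACATGGTCGCCTCAGAGTGCACGACGGCCTTCGGTCTATAAGAGATCGATCGTCCCGTTCGGGCGGCGATTACGTGTTAAGGCGCTTACGTGTCTCGTGTTGAATCTAATAGCCGTTGCATCGCGGTGTGCTGTGAGAGGA
>TRAV5*01 type=V locus=TRA anchor=165
CGTGCACCGTGTTCATCGCGCATGACGACAATCAGAATGTCATTCATACAGCAGCGGCGGGAGGCGAATTGGCGAAGTTACGGGCATTTCAGTGAACGGACCTGTGCGAGATATCCAGGTACGGTAAACCTACTTCCTGCGCGACACATAAAGCATAGCCTCGGATGTGCTGTGAGAGGA
>TRAV6*01 type=V locus=TRA anchor=165
CCTACTGCGGGCTACGTGACACCATGGGGACGATTAAAACGCTGTCGGCCGGCTGCCGAGACTGTACAATTCGCGACGCGGTCTACCCTTGAGTGCAAACGACAAATGCTTTGCGTAAGTGCGAATACAAGATTGAGTGGCAGTAAATTCCTCACTCAAGCTCAATGTGCTGTGAGAGGA
>TRAJ1*01 type=J locus=TRA anchor=9
CCCACTCCATTTGGCCAAGGCGCGGGCACATACAAAGACGCACCC
>TRAJ2*01 type=J locus=TRA anchor=9
CCAGTTGTGTTTGGCCAAGGCCAGTTAGGCAAGCGAGTTCGATGG
>TRAJ3*01 type=J locus=TRA anchor=9
GATCGGACATGGGGCCAAGGCCCACTACGCGTCCCACTGGCGAAC
>TRAJ4*01 type=J locus=TRA anchor=9
AGTATCATTTTCGGCCAAGGCACCACGATGCTGTCCTTGCGCCAG
>TRBV1*01 type=V locus=TRB anchor=165
TTTACGGGAAGAAAAGGATTCTTTATCCACTCCGTCATAGCTGGTAAAGACTTCGCAAAAATGAATGCCTATACCTCGGAGGGCTTATGCCGGCCCTCTCGGAAACTGGTCTACGCCCTAGCTGGTGCCTTTAAGTTCGTCTTCTACCAGAGGTCAAACAATGTTTGTGCCAGCAGCCAA
>TRBV2*01 type=V locus=TRB anchor=165
GATGTGCATGCTGAGAACACGAGGAACACAGGTGATCTCGGACGTGCACCTCCAAGTAGGAGGGTCAAAGACAACTTATTACTTATGTTTTCAAGGGTTGTAGTCGTTGATTTCGGATCATGTCGTTCGGTGAGTTCCAGTCCTGCGTTTGTCGGATGTCAGGGATGTGCCAGCAGCCAA
>TRBV3*01 type=V locus=TRB anchor=165
TTGCCTCTGAGATTCATCCAACAACATACAGCCTTGATCGTGCATCGAAATCCAGTAGATTTAGCCTGCATGCAACTTCCTTTACAGGACGATCCCCAGGTTGCAGTGATGGCCTGCGCGGTCAGCGACGCCCCCAGCGAAGGCCAAGGTGAGTCTAGGGAATCATGTGCCAGCAGCCAA
>TRBV4*01 type=V locus=TRB anchor=165
AGTTACGTGGTATCGGGGCGAGCCTGTCCCCAAATAAGCAAGGCTCGCGAGCGTTCGCGCCGGCTTTTTGTAGGTGAAAGGCTGCACATGAAGAAAATAAGTAGCCTTGCAATTGTCCTAGCCCAAATATTGAGCTGCCCAGCCGGTAACTCCCATCAGGAGCCGTGTGCCAGCAGCCAA
>TRBV5*01 type=V locus=TRB anchor=165
AGCCCATGCCAGAGTAGCCTGTTAAAGCATAGACTACACCTAAATCATCGAGTATCGCGTCGCCCGGGGTCAATCTGTGCGTACGGAATACCAGGAGACGCCTTTGGGACACAACGAGCGATCCTTTTGCTTCAGTGGCGGTGTAGCAGAAGAGTCGGCCCCAGCTGTGCCAGCAGCCAA
>TRBV6*01 type=V locus=TRB anchor=165
TGTGCTAACTATGAGGGGGTGAATCGTCATGCGCTATGGCTGAGCCAGCGCTCTACACGCTTTTATAGCGTCAGTTTACTTCTTGGCCGTAGCCTGGGTAATTCCTCTCAGCGACTAGCCGGGTGGATAAACATACCGGGGGCAGTTACGGCCCACCTTACCATCTGTGCCAGCAGCCAA
>TRBJ1*01 type=J locus=TRB anchor=9
TGGTTTCTGTTTGGCCAAGGCGAGCCTCTCGGCATCGAACATCTG
>TRBJ2*01 type=J locus=TRB anchor=9
CTTTTTTCTTTTGGCCAAGGCCCGGTAGTACAGCCCGCGTCGCCC
>TRBJ3*01 type=J locus=TRB anchor=9
AACACCTGCTTTGGCCAAGGCGTATTTTCCGCAGATACGTATATC
>TRBJ4*01 type=J locus=TRB anchor=9
CCGAGCCTTTTTGGCCAAGGCACAGAGCTTGGTACACATACGCCA
>TRBD1*01 type=D locus=TRB
TTGCGGGTCCGCCGC
>TRBD2*01 type=D locus=TRB
TGTATTAATGGAACG
>TRGV1*01 type=V locus=TRG anchor=165
TCTAGGCTCCACGATGCACCGGCGGGGACCCTGGCAATCGCACCCCTAGAAAACATATGGGTCTTGGACCGAAGTGCGACAGTTATATGGTATACAGTTTATCCGACCGTTGAGTGGGCTAGAGGTAGTCCGTGGTGGGCGTCAATACCGAGCGGTGCACAATTGTGTGCTGTGAGAGGA
>TRGV2*01 type=V locus=TRG anchor=165
GAAAGGAAGCGCTTGCTCTCACCCTACAAGAGAATAACTAGGATAGCAATGACCGCAAGTGGCGGGTCATCTTGTGCGCCTAATGTCTTTATAGAGGATTACCGGGGAGTCACCAGGATCCCGGCACGTTCGTCCGAGCGAAAGTTAGACTACTCTGGGATCTTCTGTGCTGTGAGAGGA
>TRGV3*01 type=V locus=TRG anchor=165
TGCTCGTCCGTAATTAACCTAGTATGGCGTAGATTGCGCTCAAAGGCCGCCAACTTGCTAAAACAAGCGCTGTCTCTATCGTTTTCCGGGCTTCATAGACCGGGGGAAGGACTTCAGTCTTTGTTGTTCAATCGCACTTGGACGTTGTCACACACCAACACACATTGTGCTGTGAGAGGA
>TRGV4*01 type=V locus=TRG anchor=165
GTCAATGATCGAATCAGCACTGAGCTTCGACGTGATGGAGTCTACTGCCATCTAGCCCTAGTCTTGTTCTCACAATTAGGGTGCACTCGAAGTGTCAGCACCCGCTTGTGCATCGGGCATAACGTCGTGCAGGCATGTTTCATTTCTGCTAAGACCCGTGTCTATTGTGCTGTGAGAGGA
>TRGV5*01 type=V locus=TRG anchor=165
GTGTCGTTACCGGTCACACATAGCCGTGCAGACCGGCGCGCCACGACGGCTGACTGGAGAAGCGCCGAAGATGGCCACGCCCATGGCTCACGCGGTGCATTCCTCTATATAGGGTATCCCACTACTAGTAAGACAGTCGTTGTTCGAGCTAAGCTTCTAGCGTCATGTGCTGTGAGAGGA
>TRGV6*01 type=V locus=TRG anchor=165
AGCCCCTCTTATTACGCTGGTGAGCTATTGTCGCATCGTAGCCCACTATGTAGTCTACTTATCGAGGTAAACGAGCTGTGTTCTCGAGATGCTGCGTCAGATCACCCTCTGACCCCAGTTACCCATATACTAGAATCGGGTGAAATTAAATTACGATCCCTCGGCTGTGCTGTGAGAGGA
>TRGJ1*01 type=J locus=TRG anchor=9
ATCAGCAAGTTTGGCCAAGGCATACCGTTTGCTTTTCGTGCGCCG
>TRGJ2*01 type=J locus=TRG anchor=9
AGGCGTGCGTTCGGCCAAGGCTTGAGATTTAGCTGGCACAGCCGG
>TRGJ3*01 type=J locus=TRG anchor=9
AGTCGATATTTCGGCCAAGGCATCAACTCTGACATACTTAGTCTA
>TRGJ4*01 type=J locus=TRG anchor=9
GCGGACAAGTTTGGCCAAGGCTGCATACGATTACTACACCCGGTC
>TRDV1*01 type=V locus=TRD anchor=165
CCAAGCGTCGTCGAGTTGATGCCCCTTGAACAGTTCCAGAAGCCCAACACAGCGTGTCGTTCTGACGGCTATTTCCACTGTTCTCGCAGCTTTGCCCGATGTGCAGACCAGCAACCAAAAGATATTCATGCTTGTGCTAGAAGTACAGCTCAACATGATGGTGTATGTGCCAGCAGCCAA
>TRDV2*01 type=V locus=TRD anchor=165
AGTTCCAGTAGTCCTGTAGCATGTGTCACCTGTTCCGGAACAGAGTGGACGAAAGCGATTCCGCCTTCACGATATACTAACCAAGCTTGTGAAATTATTTCGGTAAGATACGCTATGAACACGACGCAGTTGGCGCTCCGTAGAAAACACGGCGAAGGGAGTACTTGTGCCAGCAGCCAA
>TRDV3*01 type=V locus=TRD anchor=165
ATTTGTTCTTGCGAACGAGTCAAACATTTTCTGTTTTTCAAGGAGTTGAGGCCAGACCCACCCGGCCCTGATAATGCAGTCAACGGCTGCTATGCGATGGTAGTTTTACAGACGAGTGAAACTCTCACTGCATCCACTATGTTACGGCGGAGTGGCGAAGAGGCATGTGCCAGCAGCCAA
>TRDV4*01 type=V locus=TRD anchor=165
GAACTGCGAGTCTTCACATCGTCGGCGTCATCTGGTTCATTGCTCCATTTCACTGACGACTACATTGCAAAACGTGGTACCACGGCACTGGGTGTCTATTGTTCGCCGAAAGTGCGCATGTCTCCGAATTTCCCCTGTCACAAATTCGGTAACAAGCCGCAGTCGTGTGCCAGCAGCCAA
>TRDV5*01 type=V locus=TRD anchor=165
ACGGCACGCAGGCCTTTGTGCAACGGAGCTGTGCCAACTCAGAATTCCCCAGTGTACTCTCAAGGCCTGTTCCGCATAATTACCGGCAAGCATCGTACTTCGGAGTGCCTAGTATCTTCAACACCAAATAGCTTTCGAATTATCCTCCACCGTGGAGACTCGCATTGTGCCAGCAGCCAA
>TRDV6*01 type=V locus=TRD anchor=165
TGTGCTGCCGAGCGTTTAGTTGGTCGTAAAGAGTCCCCTTCGCTCTGGGCAGTCGACAGGAATCACTTAAATATCGACGGGTTAGTGGTGCGGATGGCATCGGAAACAGGAGATACCGCTACTGTAAGCGCCGTTCCTCGATGCGCGGCTCGGGGCTCGCGTCGTTGTGCCAGCAGCCAA
>TRDJ1*01 type=J locus=TRD anchor=9
ACGGCTCCGTTTGGCCAAGGCTACCACCTTAAGTGCATCCGCCGC
>TRDJ2*01 type=J locus=TRD anchor=9
GACAGCATGTTTGGCCAAGGCGGCAGGCGAGTTTGTAGAACGCGT
>TRDJ3*01 type=J locus=TRD anchor=9
TTCCTCGAGTTTGGCCAAGGCGGCCCACGTTCGCGACTGCCTTTC
>TRDJ4*01 type=J locus=TRD anchor=9
CACCGTGTCTTTGGCCAAGGCGCCGTTTATTCCTCAATGCCGAGT
>TRDD1*01 type=D locus=TRD
GCGGCTCTGGGCTGT
>TRDD2*01 type=D locus=TRD
ATTTTGACGATCGCG
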