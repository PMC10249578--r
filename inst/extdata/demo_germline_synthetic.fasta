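>IGHV3-74*01
TGTTACGAAAGACGCATGCAGGGTGTGGTCGGACTTCGGAGAGCGCTCCCTTGCTCGTCTAATATACGTT
CGGGAACTACGCCCGTTCGGGTGTCGTCACGTGCACTACCACCGACCCAAGTGGATCAGAGCAACAGGCG
GAACGCGTCCTGTGTACAAAACTCAATGCACACAGTGCTATATCCCGGTGCTGTAAGGCCAATATCCGCA
GGGTCCCGACCCCCTAACGATTTCTGGTGGCCTGTAGGGTCGAGAAGCATTGGGGCTCATCAAGTAATGT
ACATTGGACGGAGATGT
>IGHV4-61*01
AGTTACGCAAGACTAATGCATGGTGTGGGGGGACGGCGGAGTGCGCTGCCTTGCGGGGCTCGTACGCGAT
CAGGCAATACGCCCATTCTGCTGTCATTCTGTGCTATACCACCAACTCAGCTCGATCAGAGAATGAGAGG
GTACGGGTCCCTTGTTCATAGTTCATTGGTCACAGTGCTACGTGCCGGTGAGAAAAAGCCACTATCCGTA
TTGATAAGCCCCTCGAACGATTTTTGGTGTACTGTCGTGGCGAGAAGCTATGCATCTTTGGACCTCCTAT
TCCATGTATGGAGATGT
>IGHV4-59*01
AGCTACGCAAGACTAATGCATTTTGTGGGCGGACGTCGTGATGCGCTCCCTTGCGGGGCTAGTACGCGTT
CAGGAAGTACGCCCGTTCTGCTGTCATACTGTGCAATACCACAAACTCAGCTCTATCAGAGAAAGAGAGG
GTACGGGTCCCTTGTTCCTAGTTCATTGGTCACAGTGCTATGTGCCGGTGCTAAAAATCCAATATCAGCA
TTCACAAGCCCCTCGAACGGTTTTTGGTGTACTGTCGTGGGGAGAAGCTATGCATCTATGGACGTACTAT
TCCAGGGATGGAGATGT
>IGHV1-46*01
ATCCACGCAAGACTAATACATGGTGTCGCCGGACGTTGGAGAGCGTCTCCTCGCGCGGCTCATACACGTC
TGGCAAATTTGCCCGTTGGGGGGTCTTTCAATGGACTACCCCCAACTCAGGTTGAGCAGAAAAAGAGGCG
GTACGGGTACTATGTGCTTACCTCATTAGTCACAGTGCTATATCCTGGTGCTATAGAGCGAAAAACGGCA
CGGACAGGACCCTCTATCGACTGCTGGTGCATTGTCGTGGCGAGAGGCTTTGCATCGCAATACAAAATGT
TCCCGAGGTGGAGATGT
>IGHV3-33*01
AGCTACGAAAGACTTATGCAAGGTGTAGTCGGACGTCGGACAGCGCTCCCTTGCGCGTCCGATATACGTT
CGGGAAATACGCCCGTGCGGGTGTCGTCCCGTGCAGTACCACCGATCCAAGTGGATCAGAGCAAGAGGCG
GAACGGGTTCTGTTTACTAACCTCAATGCACACAGTGCTATATCCCGGTGCTGTAAGGCCAATATCCGCA
GGTCCCCGACCCTCTGACAATTTCTGGCTCCCTGTAGGGCCGAGAAGGATTGGCGGTCATCAAGTAATGT
TCATTGGACGGAGATGT
>IGHV4-34*01
AGTTACGTACGACCAATGCATGGTGTGTGCGGACGTCGGAGTACTCTCCCTTGCGGGGCTCGTACGCGGT
CAGGAAATACGCCCATTCTGCTGTCATTCTGTGCAATACCACCAACGCAGCTCGATCACAAAAAGAGAGG
GTACGGGTCCCTTGTTCATAGTTCATTGTTCACAGTGCTAGTCGCCGGTGCTACAAAGCAAATATCCGCA
TTGACAAGCCCCTCGAACGATTTTTGGTGTACTGTCGTAGCGAGAAGCCATGCATCTTTGGACGTACTAT
TCCAGCCGTGGAGATGT
>IGHV3-23*01
AGCTACGAAAGACTCATGCACGGTGTGGTCGGACGGCGGAGAGCGCTCCCTTGCGCGTCTAACATACATT
CGGGAAATACGCCCGTTCGGGTGTCGTCCCGTGCAGTACCACCGACCCAAGTGGATCAGAGCCGAAGGCG
GAACGGGTCCTGTGTACTAACCTTATGGCACACAGTGCTATACCCGGGTGCTGTAAGGCCAATTTCCGCA
GGGCCCAGACCCTCTAACGTTTTCGGGTGCCCTGAAGGGCCGCGAAGCATTGGGGCTCACCAAGTAATGG
TCATTGGACGGAGGTGT
>IGHV1-18*01
AGACACGCAAGACTATTACATAGTTTCGGCGGACGTCGGAGATCCGTTCCTTGCGCGGCTCATAGACGTC
AGACAAATTGGCCCGTTGGCGGGTCTTTTAATGCAGTATCCCCAACTCAGGTTGAGCAGAAAAAGTGGAG
GTACAGGTACTATGTGCTTACCTCATGGGTCACAGTGCTATATCCTGGTGCTATAGAGCGAAAATCGGTA
CGGACAAGACCCTCTAACGACTGCTGGTGCATTGTCGTGGCGAGAGGCTTTGCATCCAAATACAAAATGT
TCCAGAGGCGGAGATGT
>IGHV4-4*01
ACCTACGCAAGACTAATGCATGGTGTGGGCGGACGTCGGAGTGCGCTCCCTTGCGGGGCCCGTACGCGTT
CAGGAAATACGCCCATTCTGGTGAGGTTCCTTGCAATACCACCAACTCAGCTCGGTCAGAGAAAGAGAGG
GTACGGGTCCCTTGTTCATAGTTCAATGGTCACAGTGCTATGTGCCGTTGCTGAAAAGCCAATATCCGCA
TTGACAAGCCCCTCGCACGAGTTTTGGTGTACTGTCGTGGCGCGAAGCTATGCATCTCTGGCCGTACTGT
TCCAGGGATGGAGATGT
>IGHV6-1*01
AGCTATGAGAGGCTAACCCATAGTGTGGGCGGACGTCGGAGTGCGCTCCCTAGCGCGGCTGATTCACGTT
CGGGATATCAGACCGTTCGTGTGTCCTGCCGTGCACTACCACCAACTCAGGTTCATCAGAGAAAGAGGCG
CTCCGGGTGCTGTGAGCTTACTTCATTGGTCACAGTGCTATATCCCGATGCTCTGGCGCCCTTTGCCGCA
GGGTCAAGACCCTCTAACGACTTGTCGTACCCGGTAGTGAAGAGAATCTTTGTAGCTAAATACGTAATGT
TTCCGGGACGGAGATGT
>IGHD1-26*01
CATTTCGAGGGGGAGAAG
>IGHD2-15*01
ATCAACAAATGCCGAAGCCAAG
>IGHD3-10*01
CATACCGTTACTGGATACGG
>IGHD4-17*01
ACGCGGCCCTCCGTTGG
>IGHD6-19*01
GCTTCACAATGTATGCGAG
>IGHJ1*01
GGAATACAGGGTTGGCCCTCGCACTCGCGCCTGGGCCCACGCGGC
>IGHJ2*01
AACTCCCAACGGTGGTGGATAACCTCCGACGCCGCGCATCGTATA
>IGHJ3*01
GTGGTACCATCGTGGTTCAATCGTTCGTGGGGCCCTTCAGTTGCG
>IGHJ4*02
GTCTGCGGTTTATGGATACAGCACACCCGCACCGAAACAAAGATG
>IGHJ5*01
TTATGGCTCGTTTGGAGGCATGTCGCGATCACAGCAGGAGGTGTG
>IGHJ6*01
TCTCTGCGAGCGTGGCGAGGCACGGACGCCCCTACCAGAAGTCCT
>IGHM
GGCACCGTTGTGCTAAGGAGGACGCTCAGCCGCCCATGTTGCATCCATGATACCTATAGGACGTCTACGT
TTGACCCGTCCCCATGATATGGAGGTATTATTGATGATGTTACTGGACCG
>IGHD
GACATGAGCCGAAGGGTTTATTATTCGGGTACAAGGAGCGGCTATTACAGTTATTGTGCCGTGGTTTCTA
CAATTTTTGGCACCGAGTCCTGCCATTCCATTTAGCTCATGAATGGTCTC
>IGHG3
CTTGTACATTAGCCATATCGCTATGAGTAAGCGATTTCATCACCCAAACTATTAAAGTGACGTTTGGGAC
TTTATGAGTAGAGAAGACCGATACGCAGGATGCTGAAGGTCTGTCAACCT
>IGHG1
GGTGATCCATCTAATGTTAGTAAATGCGAGTACAGAAAGCTCAAATCGCAACAAACCCGGTCTATATACC
CGTTAGGGGACGATAAAGTTATTTCTATTTCTGGTTAAATCACCGCTACG
>IGHA1
AGGGCCAGCCCAAGATTATTAATCTGATCTGAAGAGGCTCTCGTAAGAAACGTTATTTGTGCGCCGGACG
TGGCAAGCCCTAAATAGGGAACTGCACAACGCGAGCCAGAGCTTGCTGTG
>IGHG2
GACACCGGTGTCCTTCGAGGTCTCGTCTATAAAATCTACCTGTATACACTGCTAGAGACACAGAACGTTG
GGAAGAAACCGATCATCGGAGGGGTCAGGGTCTTAACCATGGCTTTAAAC
>IGHG4
TGGGACTCACGCCCGCTGGATCCTGATGTTCGCTACGGACGATGCGAGTTCTCCCATTCCATCTACCTCA
CGCATACAAACCTCCGGTAAAGTACAACAACGATGCAAGTGCACGTAGTG
>IGHE
GCCGGGATGGTCGGTGAAGTATTCATTATGGGATGTTATGGTTTAAGGACGTCTACTACTCGTCAGCACA
CATACTGACGTCACCCATTTGTTATGGTGCGGTTTGCTTGTAACTTCGGG
>IGHA2
GGAGGTTAGCTGGACGGAGCACGCAGCGACCAGCAAATGCGCACATTTGTTAATTGCGCCGAACCTGCAA
TTTACCGCGCACCCCTTATTTTTTACAGTCACGTGTTCCCTACTAGCCAT
>IGKV1-5*01
TGTCTAGACAACTCAATGCTTAAGCACTTCTGCGCTATCCCCAGACGTCGCATACAACCAATTTTATCGC
GGGCTAGTCGGAGGTCTACAGACAACCACAAGGGCCAACTCTACCCCACTCTAAAGACCTCTCCCACCCG
CGGTCGTCCCTTAAGACATCGGCCTATCGTGAATCAACGTACCCAGATGCGCGAAATGCGAAACCATTAT
TCGTCAACCCGTCTTATGCCACGTGAAGTAGGAGTCGATATATGTATCGAGGGAGACAAACTCGAGTGTA
TCCGAGAAATACGGTGT
>IGKV3-20*01
CTTCAAGACAACTCAATGCCTTCGTACTTTTGCGCTACCCCAGGGCGTCGTAAACGACGAATTAAATCGC
GGGCTCGTCGAATGGCCAGTACAAACCTCAAGGGCGGCCTCTACTCCACTCTAAAGACCTTTCCCACCCG
CGGTCGTACTTTAGCCCCTAGACCTATCGTGACTCAACGTACTAAGATGCGTGATATGCTAAACCATGAT
TCGACAGCCCGTCCTCTTCGACGTGCAGTAGGAGTAGATATTGGTAGCGAGGGACACGGAACCGAGTCTG
TCATCGAAACCCTGTGT
>IGKV2-28*01
TATCTAGTCAACTCAATGCCTACGTACTTCTGCGCTATCCCAGGACGACGTGGACAACAAATAATGGCGC
GGGCTCGTCGGATGACCACTTACAACCACAAGGGCGGGCTCTACTACACTCTTAAGACCTTTCCCACCGG
TGGTAGTACTTTAAGACGTCGGCCTATCGTGAATCAACGTACTCAGATGCGTGATTTCCAAAACCATTAT
TCGTCAATCAATCCTCTTCTTCGTGCAGTAGGATTAGATGTCTGTATCGAGGGACATGGGCCCGATTGTA
TCCCACATACCCGGTGT
>IGKV4-1*01
TATCTTGAGAACTCAATGACGACGTACTTCAGGGCAATCCCAGCACGTCGCATACAACGAATTATATCGC
GGGCTCGTAGGAGCGCCACTCTCAACCACAAGGGCGAGCTCTACTCCACTCTAAAGACCTTACCCACCCG
CGGTCGGCCTTTAAGACCTCGGCCTTTCGTGAATCGACGTGCTCACATGCGTGATATGATGAACAATTAT
TGGTCGACCCGTCTTCAGCTACGTGCAGTAGGACCAGATATATGTATCGTGGGGCAGGGATCCGAGTCGA
TCCCAGAACGCCAGTGT
>IGLV1-51*01
ATTCTCTCGATCGCAGGACTAGACAGAACGTATCGTGAAACCATGTGTGAGCACTCGAGGTGCAACCCAT
GTCTGCTCGACTGGCCCTTGGTCCTGCGTAGACTACACACTCAGTTTGGCGTAGGACAAAATGATCCACG
TGGCACATTAGCTAACTGGCTTGTCAGCCGAGCGTGCCTACTCACGCCAGGTACGTTCTACACGGGACCA
GGTTGTAACCCTCTTAGGTGGGGCCAATCGAAAGATCCAGAAGACAAGTTGTTAGCAGTCGGTTCGACAG
GTGTTCGCATAAGGTGT
>IGLV2-23*01
ATTCTCTGGAACGCTCAACTAGAAAGAACATATCCAGAAACCATGAGAGTTCACTCGAAGTGTATCCTAT
GTCTGCTGGGTTGGCCCCAGGTCCTCCGTAAACGACAAACTCAGGCTGAGCTAGGACGAAACTATCCACG
TTGCGCACTAGCTAACTGGCGTGGAAGCCGAGCGTGCCTACTCTTGCCAGTTAGGTTCCAACCGGGACCA
GGTTGTCAACCGCTCAGAGTCGTCCGTTCGAAAGATCCCGAAGACAAGCGGGTAGCAGTCGGTTCGAGAG
GTGTTCGCCTAACCTGT
>IGLV2-14*01
AGTCTCTCGATTGCTCGACTAGACGGAACATATCCTGAAACCGTGAGATCTCACTCGAAGTGCAACCCAT
GTCCGCTGGGTTGGCCCTTGATCCTCCGTCGACAACACTCTCGGTTTTGCCTAGGTAGATACTATCCGTT
TTGCGTACTAGCTAACTGGCCTGGCAGCCTAGCGTGCCTACTCTCGCCAAGTACGTTCCAAACGGGTACA
GGTTGGCACCCGCTTAGTTGGGACCGATTGAGAGATCCCGAAGACAAGCTCGTAGCTATCGGTGAGAGAC
GTTCTCGCCTAACCTGT
>IGLV3-21*01
ATTCTCTCGGTCGATCGACTATCCAGAGCGTATCCTCAAACCATGAGATTGCACTCGTTGTGCAACCCAT
CTCTGCTGGGGTGGCCCTGGATCCTCCGTAGACAAAACACTCAGTTTGGCATAGAAGAAGATGATCCACG
TTGCGCGCTAGCTACCTGGCTTGCCAGCCGAGCGTTCCTACTCTCGCGAGGTACGTTCCAGAAGGGACCC
GGTGCTCACCCGCTTAGGTGGGACGACTTCAGAGATCCCGAAGACAAGCAGGTAGCAGTCGGTTCGAGAG
GTTTTCGCCTAAACTGT
>IGKJ1*01
GGAAAGGTCTTTCGCCGCGTTCGCTACCTTCAAAACCGTG
>IGKJ4*01
ATCACGGCATTTCATGAATTGCCCAAGCCCTACCAACTCA
>IGLJ1*01
TCCAAGTCACTTCACCCGTTCACATATCCTGTGTACGCGT
>IGLJ2*01
TACCGCACAGTTCTATGTGATGGGCTTTGGTGGGGTGGGT
>IGLJ3*01
AGGAAAAATATTCCATAGTGCTACTCGACGTAAGTATGCT
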