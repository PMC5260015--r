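# The 50 representative 9 bp DNA targets (5'->3') used to build the published
# training corpus: 40 sequences were used for training and 10 held out for testing.
sequence
CGAAATCGC
GCTTATACT
GCAGCCTTT
TTTGCTTCA
CATTTAGTG
CATGTATGA
AGGGCAGCG
TAGTCCATT
TTATTATGG
GGAGGAGGA
GTGGCGGGC
CCATATGCG
CTTACTCTG
GGAGCGATC
ACTCAGCTC
TAAGCTCAA
GTGTATATA
GCCCACGAA
ACGCAACAG
GGGGGGGGG
TGGTGGGGA
ACTACGCTA
GACCCATAC
CGCTTATTA
TGGTGTCCG
TCGGCGTGA
TAATGTGGT
AGCTATTTC
TCCTCGTGT
GTTGTTGTT
CAATCAGAT
CCAGAGTCC
CGGAGAAGG
GTTTCTCTC
GCCGCCGCC
TGCAATTGA
GTGATAATC
GCTAGTTAG
ACGATTAGG
GCAGCAGCA
ACCGAGCTA
TTAAGAGAG
CGCAGCTAG
ATATTCGAG
GAGGAGGAG
TGCAGCTAT
GAACGAAGA
CCCCAACTG
TTCGGGCAA
GGCGGCGGC
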