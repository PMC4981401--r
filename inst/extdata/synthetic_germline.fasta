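>IGHV1-2*01|V|IGHV1|cdr3_anchor=95
GAGCCCGCTGTCGCTATTTACGGTCGATACCATCCAAGAGGAGCTCCTTTCGGTCGACGCCTGATATTATGACTCTCATG
GCGGGTGGTTGCCTGTGTGGATCC
>IGHV1-18*01|V|IGHV1|cdr3_anchor=95
TACTGTCGCGTTATGTGGCATCAACCTATGCCAACTTAAGTGCAGCGCGTAGTGGCTCCCAAATCTGGTATTCCGAAGTC
GCTTACTCGATTTTGTGTTGTTGT
>IGHV1-69*01|V|IGHV1|cdr3_anchor=95
CCCCCTCATCCAGCCGGCGCCGCAAATTTATGATCGAAAAGGAAAGCAGGAAAATCTGTATAGAGGTGCGTCGACATAAG
GGAGCACAAGATGCCTGTCCACCA
>IGHV3-23*01|V|IGHV3|cdr3_anchor=95
ATAGGAAGCAGCTTTTCCGGCCGATACGGATATCTCGTAGACTGGCAACCTTCCGCCCTCTGGGCCGGACGAGAAGTAGT
ATGGCTAAAAGTAACTGTCCAGAG
>IGHV3-30*01|V|IGHV3|cdr3_anchor=95
GGGCGGGGATTGCGGGAACGCCCAATGTTGTGAAGGACGCCGCTCATTTGGAGGAGGTCCGTCACCGCTTAGCGCGAGGT
ACACGAACAGAATTCTGTAGCCGC
>IGHV3-48*01|V|IGHV3|cdr3_anchor=95
ATATGGTTAGTTGGCTTAACAGGCCCAAAAAGACGCTGTGTCCAACGTACTGCCTGGTATCCTTTCCGTTTCTTTCACGG
TCCCGATCTGGGCATTGTGAGGAT
>IGHV4-34*01|V|IGHV4|cdr3_anchor=95
TGAAAACGCAGCTCCTGATAGGTGGGGGCATATGTGATATCTACATAGTAGCGGGATCCGCGCCTGCCCCGTCCAGTGGT
CATTTCAATACTACGTGTCCACAC
>IGHV4-59*01|V|IGHV4|cdr3_anchor=95
TGTTCGACGATCGATCGATCGTCGATGCCCCGAATTCTAGCTCGAGCCCACCGACGAGAGTCGATACTGCGACCTGTCCT
CGGGGGCAACATCTTTGTAAGGGA
>IGHV4-59*02|V|IGHV4|cdr3_anchor=95
AGTTCGACGATCGATCGATCGTCGATGCCCCGAATTCTAGCTCGAGCCCACCGACGAGAGTCGATACTGCGACCTGTCCT
CGGGGGCAACATCTTTGTAAGGGA
>IGHD2-2*01|D|IGHD2
GGTCATCTCGGC
>IGHD3-10*01|D|IGHD3
AAGTGTAACTTGCC
>IGHD3-22*01|D|IGHD3
GCGAATGTTGCCACGA
>IGHD6-19*01|D|IGHD6
CGCATCGAAGTATC
>IGHJ4*01|J|IGHJ4|cdr3_anchor=12
ACTCTGGTTGGGTGGGGCCTA
>IGHJ5*01|J|IGHJ5|cdr3_anchor=12
CCCAACCCGCCTTGGGGCCTC
>IGHJ6*01|J|IGHJ6|cdr3_anchor=12
CCGATTGACGGCTGGGGCGCA
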