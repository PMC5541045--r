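sequence	orientation	family
CGTCGTCTGACCCTTTTATCGCAAACCTAATAAG	forward	DRF01
AAATTAGAAACGATCCGTGTTTAAAAATCCCGCAA	forward	DRF02
TGTTACCATAGCTCAGATCTAAACCTTGGTATGAT	forward	DRF03
CATTTCCAATTGACGATACGTTGGTCGTGGTCA	forward	DRF04
CACTGTGTATATAATAAACAAGTCTAATCTTCGA	forward	DRF05
ACGCTTATTAAATGCCTAACTTAAATGAATACT	forward	DRF06
GGTTTCGGGCTGTATTCTTTAAAACTCT	forward	DRF07
GTTAGGATCGGCACTGATTAGCATCAAA	forward	DRF08
GTAGAGTCAAAACGGTTGTTTGCATGTTAACCAAACC	forward	DRF09
CCGTACATTTACCATGGTCTGCTAAAAG	forward	DRF10
GGCATAGAGATTTTTCTGTCTTTTACAATTTTG	forward	DRF11
CGAGCATAGACGGTATATGCCCCGGAGAGAGAATG	forward	DRF12
TGTATCAATTAATTGTCCGTTCTCCCCAC	forward	DRF13
TGGGTGGATCGGGTTGTCTAAGGATGCTGCGTAAG	forward	DRF14
CACGAATAAGTGAATAATATGGTTCCGTAGGAC	forward	DRF15
TTCGTTCGGCTCTGTATGGTTGTGTGTCTAAATTC	forward	DRF16
GATGAAGAATTAGGAAATACCTGACAATTTCCTGAGC	forward	DRF17
AAAGACAGTGGTTGTATGAGTTGCAAGTC	forward	DRF18
ATGCTATCTTAGGAAAATTGCTCTACGATG	forward	DRF19
TAAAGTACTTCCCAGTGTGATAACTTAATTGATTGT	forward	DRF20
GATCTTGGCAACTAAATACGGATAGCCTTCA	forward	DRF21
ATGAATTTATGATCTCGGTGTGGTTCGA	forward	DRF22
TGACAAATAGATCCTCCTACGACTTCACAGTCAACC	forward	DRF23
ACACAAGAAGGTGGACCAATTGAGAGGTTG	forward	DRF24
CACGATAACCCATTAACCATCCGATGTCCACAGTTA	forward	DRF25
CTGATGCTAAGTAGTTGTTACATAACCTGCGTGGAGT	forward	DRF26
TCTGGTTCACTTTGCTCTCACGTAGCAATTTATGCAT	forward	DRF27
TCGTAGCAGAAGGGCGAACATAGTAGCTGTTACAATA	forward	DRF28
AGTGGCTCCGCCAACCGCGCCATTTATTG	forward	DRF29
CCTAATCTTCAAACTTACAGTTGAAAAAT	forward	DRF30
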