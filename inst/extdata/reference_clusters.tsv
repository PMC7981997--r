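cluster	nodes	edges	genes
1	13	58	CCND2,TOP2A,CDK4,TTK,PLK1,CCNA2,CCND1,CCNB1,PLK4,CDK1,CDC25C,CHEK1,AURKA
2	5	10	CDK2,CDC25A,CCNE1,WEE1,CCNE2
3	5	8	JUN,ESR1,EGFR,NR3C1,ESR2
4	6	8	PTK2,IGF1R,CASP8,PRKACA,CASP7,BCL2L1
5	3	3	PPARA,CREBBP,RXRA
6	3	3	EDNRA,ECE1,EDNRB
7	8	10	MAPK3,MAP2K4,CASP9,FGFR3,FGFR2,MAPK9,TNF,MAPK10
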