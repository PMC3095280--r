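name	sequence	orientation	published_degeneracy
PHYdeg-F	CAYTAYYCIGCIACIGAYATHCC	forward	768
PHYdeg-R	CRCAIGCRTAICKARIGGRWAIGG	reverse	16384
PHYABnondeg-F	GCATTATCCTGCTACTACTGATATT	forward	0
PHYAdeg-R	CAWGCATACCTWAGMGGRAAI	reverse	64
PHYBdeg-R	AACAACIAIICCCCAIAGCCTCAT	reverse	64
1010-F	GTTYTTGTTTAAGCARAACCG	forward	4
1910-R	GAGTCWCKCAGAATAAGC	reverse	4
1910-F	AGCTTATTCTGMGWGACTC	forward	4
2848-R	TAACCCKCTTRTTTGCAGTCA	reverse	2
PHYC-1R-DFCI	GGTCCGCCTGATTGAGACTGC	reverse	0
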