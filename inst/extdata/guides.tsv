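name	protospacer
Ptch1.1	CTGGCCGGAAAGCGCCGCTG
Ptch1.2	TCAGAGACTCTTATTTAAAC
Ptch1.3	GTTGTGGGTCTCCTCATATT
Nf1	AGTCAGCACCGAGCACAACA
Pten	AAAGACTTGAAGGTGTATAC
Trp53	ACAGCCATCACCTCACTGCA
gNT	GCGACCAATACGCGAACGTC
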