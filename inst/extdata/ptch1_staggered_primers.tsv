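name	fwd_primer	rev_primer
amp1	CTCACTGATTTACAACCAAGGC	CATCAAACACAGTAAAGGGAAGG
amp2	GCACCCCAAGTCTCATTCAG	GTCTCGAGATTAGCTGCCTTT
amp3	CACACTGCTGTCCAGAGGG	ACTGGCCAGCCATGCAAAC
amp4	CCTGGTCCCTAGAGTACAG	CGCCTGATCGCTTACCTTC
amp5	GGTTCCAGTCCGAGGGAG	CAAGGGCTTCTCGTTGGCTA
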