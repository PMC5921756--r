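name	sequence	region	amplicon_bp	dist_from_3prime_bp
MOR_5F	CGACCGTTGTCTGATTTTGTGA	5prime	81	1671
MOR_5R	GGCCATTTTCAGAACCCCTAA	5prime	81	1671
MOR_3F	GCTTCGAGCAGCAGTTGAAGAA	3prime	80	450
MOR_3R	CTTTTGACATGTGTGCAAGTT	3prime	80	450
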