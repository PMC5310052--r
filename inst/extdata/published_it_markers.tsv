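marker_id	forward_primer	reverse_primer	intron_A	intron_B	intron_D	intron_V	reported_type
CINAU687	ACAGCTCATCATGCAGGACA	GTCACTGTCTTGAGCAAATGGA	632	545	687	433	I
CINAU648	AGCCTCTCCTCCCTCAATCT	TGCTTCCACCTCAAATTGAACAT	269	308	281	233	II
CINAU737	AAACGAGCTTTGCATGGAGG	CTTTGCATGTTGAGAAGGACAA	339	146	340	119	III
CINAU665	GCTCGGATGCAATTATTGTTGA	ATGGTCCTTCGCAGCTGTTA	639	575	576	508	IV
CINAU735	TGAAGATCGTGTTCCTTCCTCTC	ATGCTTTCTTCATCCCCTGG	1583	1600	939	659	V
CINAU646	CATCGGTACTACGGGCGATT	GCGGGTACTTCATCCTCAT	298	304	307	445	VI
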