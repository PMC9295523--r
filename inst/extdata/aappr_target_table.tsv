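# Curated hypothetical RNA-target table for the twelve chloroplastic PPR
# proteins (AaPPR set) of Agave angustifolia: per protein, the degenerate
# binding pattern compiled from its PPR code and every candidate target found
# in the annotated chloroplast gene set. ir_duplicate marks RNAs produced from
# genes duplicated in the inverted-repeat regions (both copies encode the same
# RNA; hits are reported once).
ppr_id	pattern	gene	context	ir_duplicate	target_sequence
AaPPR1	U[AU]UUU[AU]U[CAU][AC]U[AU]UU[ACGU][ACGU]	ycf1	CDS	FALSE	UAUUUUUCAUUUUCA
AaPPR2	[ACGU][ACGU][UCG][AU][UCG][UCG]A[UCG]G[UCG][AU]GAU[ACGU]	rpoC1	intron	FALSE	UCUUUUAGGGAGAUA
AaPPR2	[ACGU][ACGU][UCG][AU][UCG][UCG]A[UCG]G[UCG][AU]GAU[ACGU]	rps12	intron	TRUE	GCUUGGAGGGAGAUC
AaPPR5	[ACGU][CG]A[AU]GAAAA[AU]G[ACGU][AU]A[ACGU][GU]	trnK-UUU	intron	FALSE	AGAAGAAAAUGGAAUU
AaPPR6	[UC][GC][GC]A[CU][CA]UAG[GU]	rps16	intron	FALSE	UCGACAUAGU
AaPPR6	[UC][GC][GC]A[CU][CA]UAG[GU]	petN	CDS	FALSE	UGGAUAUAGU
AaPPR6	[UC][GC][GC]A[CU][CA]UAG[GU]	atpE	CDS	FALSE	UGGAUAUAGG
AaPPR10	[ACGU]C[ACGU]UUCC[ACGU]CC	rpoC1	CDS	FALSE	UCCUUCCUCC
AaPPR10	[ACGU]C[ACGU]UUCC[ACGU]CC	psbC	CDS	FALSE	GCGUUCCCCC
AaPPR10	[ACGU]C[ACGU]UUCC[ACGU]CC	petA	CDS	FALSE	UCUUUCCCCC
AaPPR10	[ACGU]C[ACGU]UUCC[ACGU]CC	rrn23	exon	TRUE	GCGUUCCGCC
AaPPR11	[UC][UC][ACGU]A[ACGU]U[ACGU][ACGU][ACGU][ACGU][ACGU][ACGU]C[ACGU][UC]UCUU[CU]U	ycf2	CDS	TRUE	UUCAAUCCUUUUCCUUCUUCU
AaPPR13	[GU][ACGU][ACGU]C[ACGU][ACGU]G[ACGU][ACGU][ACGU]AUGU	atpA	CDS	FALSE	UAUCCAGGAGAUGU
AaPPR13	[GU][ACGU][ACGU]C[ACGU][ACGU]G[ACGU][ACGU][ACGU]AUGU	rps14	CDS	FALSE	UGGCAAGAAAAUGU
AaPPR13	[GU][ACGU][ACGU]C[ACGU][ACGU]G[ACGU][ACGU][ACGU]AUGU	trnI-GAU	intron	TRUE	UGACCCGGAGAUGU
AaPPR13	[GU][ACGU][ACGU]C[ACGU][ACGU]G[ACGU][ACGU][ACGU]AUGU	ycf1	CDS	FALSE	UCUCAAGCAUAUGU
AaPPR15	UUG[CU]CGC	rbcL	CDS	FALSE	UUGCCGC
AaPPR15	UUG[CU]CGC	rpl33	CDS	FALSE	UUGUCGC
AaPPR18	UC[GC]UAU[AU][CU][ACGU]G	ycf2	CDS	TRUE	UCCUAUACGG
AaPPR18	UC[GC]UAU[AU][CU][ACGU]G	psbD	CDS	FALSE	UCCUAUUUGG
AaPPR18	UC[GC]UAU[AU][CU][ACGU]G	psbC	CDS	FALSE	UCGUAUUCUG
AaPPR18	UC[GC]UAU[AU][CU][ACGU]G	psaB	CDS	FALSE	UCGUAUUUGG
AaPPR18	UC[GC]UAU[AU][CU][ACGU]G	ndhG	CDS	FALSE	UCCUAUUUUG
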