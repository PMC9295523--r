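# PPR code table: nucleotide preference of a PPR motif given the amino acids
# at its 5th and last positions. Compiled from the canonical published
# combinations for P- and S-type motifs (the strong determinants TD->G, TN->A,
# SN->A, ND->U plus their well-supported degenerate variants). Pairs absent
# from this table carry no specificity information and are treated as the full
# set ACGU. nucleotides column lists the preferred set in A<C<G<U order.
aa5	aalast	nucleotides
T	D	G
T	N	A
S	N	A
S	D	G
G	N	A
G	D	G
N	D	U
N	S	C
N	N	CU
N	T	CU
S	C	A
T	S	AG
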