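---
title: "Methods: PPR discovery, classification and RNA target prediction"
author: "pprscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPR discovery, classification and RNA target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprscout)
```

## The scientific problem

Pentatricopeptide repeat (PPR) proteins are nucleus-encoded RNA-binding
proteins built from tandem arrays of a degenerate ~35-residue helical
motif. Each motif contacts one nucleotide of a single-stranded RNA, and
the amino acids at two positions of the motif — the 5th and the last —
largely determine which nucleotide is preferred (the *PPR code*). Plant
genomes carry hundreds of PPR genes; their products govern organellar RNA
metabolism (stability, splicing, translation) and, for the DYW class,
C-to-U RNA editing. `pprscout` implements a complete discovery pipeline
for transcriptome assemblies: ORF extraction, motif-array assembly and
filtering, subfamily/class assignment, DYW-domain grading, chloroplast
localization, compilation of per-protein binding patterns via the PPR
code, search of an annotated plastid gene set for candidate targets, and
qRT-PCR quantification — plus a synthetic-data generator so that every
stage is testable offline with known ground truth.

## ORF model

ORFs are the longest stop-to-stop intervals per reading frame on both
strands, trimmed to the first ATG where an upstream stop exists
(`completeness = "complete"` when both the start and a downstream stop
are present). Segments open at the 5' end are `5'partial` and reported
untrimmed, since the true start may lie upstream of the assembled
fragment; segments lacking a downstream stop are `3'partial`; a frame
with no stop yields a single `internal` segment. Stop-bounded segments
without any methionine are not reported. The retention threshold is 31
amino acids, the conventional minimum for short PPR fragments.
Coordinates are 0-based half-open internally and 1-based inclusive in all
user-facing output (FASTA headers, TSV reports); translating the reported
interval in the reported frame reproduces the peptide exactly, which the
test suite asserts as a round-trip property.

Split ORFs (one motif array interrupted by a frameshift) may be joined
when they share a strand, the nucleotide gap is at most `max_gap_nt`, and
the concatenated motif array remains tandem. "Structural continuity" has
no standard quantitative definition, so the package makes the bound
explicit and configurable; the default of 90 nt is about one PPR motif,
the largest interruption that still reads as a continuation of the same
array. The junction inserts `ceiling(gap/3)` `X` residues to preserve
register. Joined products are chimeric reconstructions, not observed
molecules: they carry a `hypothetical` flag and are excluded from final
tallies; joining is pairwise only (no transitive chains).

## Motif arrays and filters

Motif hits arrive as tabular output of profile searches (a plain TSV
dialect and HMMER `domtblout` are both read). Three strict score cutoffs
govern retention, reflecting how discriminative each profile family is:
`> 0` bits for the ordinary motifs, `> 10` for the short SS motif and
`> 30` for the DYW domain. The thresholds are strict at the boundary
(a score of exactly 10 fails). When a table carries E-values, hits above
`1e-10` are additionally removed; tables without E-values are governed by
scores alone, since different producers report different statistics.

Overlapping hits are resolved greedily: descending score, ties to the
leftmost start and then catalog order. Greedy resolution mirrors
first-pass annotation tooling, is deterministic, and runs in `O(n log n)`.
It is *not* globally optimal for overlap chains (A–B, B–C overlapping
where B outscores either neighbour but not their sum); the test suite
keeps an exact maximum-weight interval oracle and verifies that greedy
attains the optimum on the redundancy structure the filter actually
exists for — cliques of mutually overlapping hits reported by several
profiles at one locus — while the greedy trace itself is checked
independently on dense random inputs.

An array survives validation when it has more than one motif (single
motifs are discarded unless they are a DYW domain that retains at least
the PG box), its summed score strictly exceeds 40 bits, and no adjacent
pair of motifs is separated by more than `max_intermotif_gap` residues.
The default gap of 50 aa (~1.4 motif lengths) tolerates linker drift
while still rejecting scattered, non-tandem hits; it is reported in the
output so downstream users can audit it.

## Subfamily and class assignment

P-subfamily proteins carry only canonical P motifs; any PLS-triad variant
(P1/L1/S1, P2/L2/S2), SS, E or DYW motif — or a graded DYW/E+ domain —
places a sequence in the PLS subfamily. Class follows the C-terminal
composition: `DYW` for a full deaminase domain, `E+` for a truncated
domain that keeps the PG box (with at least one upstream PPR motif), `E2`
when E2 motifs are present without a DYW domain, `E1` for E1 without E2,
and `PLS` otherwise. The terminal-composition rules for E1/E2/E+ are
named but not formally specified in the primary literature; the rules
here follow the established classification scheme for PLS-class
proteins and are deliberately simple, total and deterministic: the
assignment is a pure function of the array and the DYW grade, so
permuting the cohort cannot change any label. An SMR domain is recorded
as an auxiliary annotation rather than a motif, so SMR-bearing P proteins
remain in the P subfamily.

## DYW domain grading

The DYW deaminase domain carries three conserved regions: the PG box
(24 columns), the active site (32) and the C-terminal region ending in
the eponymous D-Y-W (25). Each region is modelled as a position weight
matrix built by count-and-normalize with an additive pseudocount
(default 0.1; it must be positive so every log-odds is finite). The
background is uniform (1/20) by default and overridable with dataset
frequencies.

Scanning is FIMO-style: each window scores the sum of per-position
`log2(P/bg)`; p-values are exact tail probabilities of the
integer-scaled score (1000 units per bit) under the background,
computed by dynamic programming over the full score distribution.
The DP is computed once per matrix and cached for the session.
Non-standard residues contribute the background probability, i.e. a
neutral zero score. The test suite checks the DP against exhaustive
enumeration at widths ≤ 3 (where all `20^w` windows can be listed) and
against Monte-Carlo tail estimates at full region widths.

A candidate C-terminus grades `full` when all three regions hit at
`p ≤ 1e-5` with their best hits in PG < active < C-terminal order;
`truncated_with_PG` when the PG box hits but the ordered triple does
not; `absent` otherwise. Region *order* is enforced but exact offsets are
not, because the documented within-domain coordinates are internally
inconsistent; the region widths are treated as authoritative and the
offsets (1, 68, 112 in a ~136-residue domain) as hints only. Grading is
monotone: appending the missing regions to a truncated domain can only
upgrade it.

The packaged region alignments
(`inst/extdata/dyw_regions_synthetic.tsv`) are synthetic stand-ins, not
curated biological alignments: they embed the field's hallmark residues
(the PG dipeptide, the H..E/C..C deaminase signature, the terminal DYW)
at the correct widths with light column variation. They parameterize the
scanner and the generator; analyses of real data should substitute PWMs
derived from real domain alignments via `buildPwm()` or `readPwm()`.

## Orthologs and localization

Best ortholog hits take the highest bitscore per query (ties: lowest
E-value, then lexicographic subject id); queries whose best hit falls
below 50% identity are dropped — non-strict, so exactly 50.0% survives.
Localization prefers targeting-signal predictors: agreement between two
predictors is a consensus call, and a single confident predictor is
treated as consensus (logged), since discarding it would waste the only
available signal. Otherwise the ortholog title is scanned for the
keyword `chloroplast` (case-insensitive substring, so RefSeq's
"chloroplastic" matches). Everything else is `unknown`.

## The PPR code and target search

For each code-bearing motif — the P- and S-type motifs P, P1, P2, S1,
S2, SS; L-type and E/DYW motifs do not contact RNA bases — the residues
at motif positions 5 and last are read and looked up in the packaged
code table (`inst/extdata/ppr_code.tsv`), which compiles the canonical
published combinations (TD→G, TN→A, SN→A, ND→U and well-supported
degenerate variants). Unknown pairs and truncated motifs degrade to the
full set `[ACGU]` rather than failing: an uninformative motif should
widen the pattern, not invalidate it. The table is an editable TSV so a
different code compilation can be swapped in.

Motif *i* maps to nucleotide *i*, 5'→3', with no terminal offset —
forced by the observation that pattern length equals target length in
the curated target table. Patterns render in a bracket dialect
(singletons bare, sets bracketed); patterns compiled from the code list
sets in A<C<G<U order, while parsed patterns preserve the printed group
order verbatim so that round-trips reproduce the input byte for byte.

The search substrate is the annotated gene regions of the plastid genome
(CDS, introns, exons of tRNA/rRNA genes) on the RNA sense strand only;
intergenic DNA and antisense windows are not scanned, mirroring a search
of "the genes encoded by the chloroplast genome". All ungapped windows
satisfying every position set are reported, overlapping windows
included, annotated with the feature context at the window midpoint.
Genes duplicated in the inverted repeats occur as two identical copies;
they are searched once and hits flagged `ir_flagged`, following the
asterisk convention of the curated table. Proteins with more than 60
distinct targets are flagged promiscuous and dropped from the headline
report — at that density a short, degenerate pattern is matching by
composition rather than specificity.

## qRT-PCR quantification

Relative expression uses the 2^−ΔΔCt method with the green-leaf tissue
(GL) as calibrator and actin, tubulin and 18S rRNA as references.
Technical replicates are averaged at the Ct level; with several
reference genes the per-gene mean Cts are averaged arithmetically, which
is equivalent to a geometric mean of the linear reference quantities
(the aggregation rule is recorded in the output metadata since the
choice between pooled and per-gene aggregation is not standardised).
The calibrator maps to exactly 1 by construction, adding a constant to
every Ct changes nothing, and removing one cycle from the target in one
tissue exactly doubles that tissue's value — all asserted as tests.
Amplification efficiency from a standard-curve slope is
`(10^(−1/slope) − 1) × 100`, acceptable between 90 and 110%.
Per-group ANOVA/Tukey lettering is out of scope; the output carries
group means ± SEM for external statistics.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the package targets:

* **Cohort**: the default class mix is the observed composition of the
  1581-sequence *Agave angustifolia* cohort (P 758, E2 344, PLS 227,
  DYW 176, E+ 63, E1 13, as exact fractions), with 35-residue motifs.
  P proteins carry 3–12 P motifs; PLS proteins carry 2–4 P1-L1-S1 triads
  plus the class-defining C-terminus; DYW/E+ classes append a full or
  PG-box-only domain built from the packaged region consensi. Code pairs
  are planted at motif positions 5 and last, drawn from the code table.
  Hit scores are `base + N(0, score_noise_sd)` with a default noise of
  1 bit; tests of exact label recovery use zero noise.
* **Genome**: gene records drawn from standard plastid nomenclature
  (psbA … ycf2), 300–1500 nt of uniform composition, introns with
  probability 0.3, and the four inverted-repeat duplicates observed in
  the *A. angustifolia* plastome (rps12, rrn23, ycf2, trnI-GAU)
  duplicated verbatim. Planted target windows are rejection-sampled to
  avoid overlapping a previous plant, so every truth record survives;
  sites are drawn uniformly from the pattern's position sets.
* **qPCR**: planted per-tissue folds (GL 1, GM 0.6, AL 4, AM 1.8 —
  leaf-dominant albino overexpression, the regime the assay is meant to
  resolve) via `ct = base − log2(fold) + N(0, 0.2)` cycles, three
  technical replicates, references constant across tissues.

Every generator is a pure function of `(spec, seed)`: sub-seeds are
derived per artifact section, the caller's RNG stream is restored, and
regeneration is byte-identical. What the generator does *not* emulate:
real motif sequence divergence (all motifs share one scaffold), codon
usage, assembly artifacts and fragmentation, paralog families, biased
plastid base composition, or partial/contaminating ORFs. Passing tests
therefore demonstrate that the *logic* of every stage is correct under
known truth, not that profile search or classification thresholds are
well-calibrated for any particular real transcriptome.

## Numerical choices and problem sizes

Integer score scale 1000 per bit for exact p-values; PWM pseudocount
0.1; uniform amino-acid background; strict inequalities at every score
threshold; non-strict at the identity threshold; ties in best-hit
selection broken by E-value then subject id; greedy overlap ties by
leftmost start then catalog order. The test suite runs at sizes chosen
to finish in seconds while still exercising every code path: cohorts of
10–200 sequences, 5 kb genes for brute-force search equality, exhaustive
PWM enumeration at widths ≤ 3, 50 000-draw Monte-Carlo tails at width
32, and 100-seed recovery studies for qPCR folds and background match
rates.

## Known limitations

* The ORF model is deliberately minimal (no coding-potential score); it
  is a compatible stand-in for dedicated ORF predictors, not a
  replacement.
* The packaged PPR code is deterministic sets, not the probabilistic
  scores some prediction servers use; borderline specificities collapse
  to degenerate sets.
* The DYW PWMs shipped with the package are synthetic; real-data use
  should supply PWMs from curated alignments.
* Localization inference trusts predictor consensus and RefSeq title
  keywords; it does not model transit peptides.
* Joined ORFs are reported but never enter final tallies; if a genuine
  split gene is of interest it must be inspected manually.
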