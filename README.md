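# pprscout

Discovery, classification and RNA target prediction for
pentatricopeptide repeat (PPR) proteins.

## What it is for

PPR proteins are nucleus-encoded RNA-binding proteins made of tandem
~35-residue helical motifs, one motif per bound nucleotide. In plants
they run much of organellar RNA metabolism — transcript stability,
splicing, translation and, for the DYW class, C-to-U editing — which
makes them central to chloroplast biogenesis and to albino phenotypes
where biogenesis stalls. `pprscout` is for researchers mining a
transcriptome assembly (typically of a non-model plant) for PPR genes
and asking what their plastid RNA targets might be. It provides, as a
tested R package:

* six-frame ORF extraction with completeness labels, and joining of
  frameshift-split ORFs (`extractOrfs()`, `joinOrfs()`);
* ingestion of profile-search hit tables (plain TSV or HMMER
  `domtblout`), score filtering and resolution into tandem motif arrays
  (`readHitTable()`, `filterHits()`, `resolveOverlaps()`);
* subfamily (P/PLS) and class (PLS/E1/E2/E+/DYW) assignment with
  explicit discard reasons (`classifyArray()`, `annotateCohort()`,
  `summarizeFunnel()`);
* DYW-domain grading by PWM scanning with *exact* p-values
  (`buildPwm()`, `scanPwm()`, `gradeDyw()`);
* ortholog best-hit selection, identity filtering and chloroplast
  localization inference (`selectBestHits()`, `inferLocalization()`);
* compilation of the PPR code into degenerate nucleotide patterns and
  search of an annotated plastid gene set, with inverted-repeat
  deduplication and promiscuity flagging (`pprPattern()`,
  `searchTargets()`, `flagPromiscuous()`);
* qRT-PCR relative quantification by 2^−ΔΔCt with multi-reference
  normalization and efficiency checks (`ddct()`,
  `efficiencyFromSlope()`);
* a synthetic-data generator with complete ground truth so every stage
  is testable offline (`syntheticSpec()`, `genPprCohort()`,
  `genPlastidGenome()`, `genCtTable()`), and an end-to-end driver
  (`runPipeline()`).

## The core models

**PPR code → degenerate pattern.** For each code-bearing motif (P, P1,
P2, S1, S2, SS) the residues at motif positions 5 and last select a
nucleotide set: TD→G, TN→A, SN→A, ND→U and their degenerate variants;
unknown pairs give the full set. Motif *i* binds nucleotide *i*, 5'→3',
so a protein's array compiles to a pattern such as `UUG[CU]CGC`, matched
set-wise against every window of each annotated plastid gene (sense
strand, overlapping windows included).

**Exact PWM p-values.** A window scores `Σ_j log2(P_j(a)/bg(a))`. With
scores scaled to integers (1000 per bit) the full null distribution of
a background window is computed by dynamic programming, so the reported
p-value is the exact tail probability — the same construction FIMO
uses. A DYW domain grades `full` when the PG box, active site and
C-terminal regions all hit at `p ≤ 1e-5` in order, `truncated_with_PG`
when only the PG box survives, else `absent`.

**2^−ΔΔCt.** `ΔCt = Ct_target − mean(Ct_references)` per tissue,
`ΔΔCt = ΔCt(tissue) − ΔCt(calibrator)`, relative expression
`2^−ΔΔCt`; the calibrator is exactly 1 by construction.

## Worked example

Match a compiled pattern against a gene and run the synthetic
end-to-end pipeline:

```r
library(pprscout)

tt <- aapprTargetTable()            # curated patterns + targets
searchTargets(tt$pattern[tt$ppr_id == "AaPPR15"][1],
              plastidGeneSet(
                data.frame(record_id = "rbcL", gene_name = "rbcL",
                           ir_duplicate = FALSE),
                c(rbcL = "AAGGUUGCCGCGGAA")),
              ppr_id = "AaPPR15")
#>    ppr_id gene_name feature_context match_start matched_sequence ir_flagged
#> 1 AaPPR15      rbcL            exon           5          UUGCCGC      FALSE
```

The pattern `UUG[CU]CGC` finds its binding site at position 5 of the
rbcL transcript; the matched window `UUGCCGC` satisfies every position
set, and the context is the feature type at the window midpoint.

```r
spec <- syntheticSpec(seed = 7, n_sequences = 120, score_noise_sd = 0)
res <- runPipeline(spec)
res$funnel$by_class
#>   subfamily ppr_class  n       pct
#> 1         P      none 63 52.500000
#> 2       PLS        E2 24 20.000000
#> 3       PLS       DYW 16 13.333333
#> 4       PLS       PLS 13 10.833333
#> 5       PLS        E+  4  3.333333
head(res$qpcr[, c("tissue", "dd_ct", "rel_expr")], 4)
#>   tissue      dd_ct  rel_expr
#> 1     GL  0.0000000 1.0000000
#> 2     GM  0.7483932 0.5952662
#> 3     AL -1.4876783 2.8043731
#> 4     AM -0.7656119 1.7000909
```

The funnel reports the recovered subfamily/class composition of the
planted cohort (the generator draws classes at the default study mix);
the qPCR table normalizes each tissue to the green-leaf calibrator —
here the albino-leaf tissue is ~2.8-fold over-expressed for this gene
under the planted folds plus measurement noise.

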