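toy_gene_set <- function(seqs, ir = NULL, features = NULL) {
  genes <- data.frame(record_id = names(seqs), gene_name = names(seqs),
                      ir_duplicate = FALSE, stringsAsFactors = FALSE)
  if (!is.null(ir)) {
    for (g in ir) {
      genes <- rbind(genes, data.frame(record_id = paste0(g, "#IR"),
                                       gene_name = g, ir_duplicate = TRUE,
                                       stringsAsFactors = FALSE))
      seqs <- c(seqs, stats::setNames(seqs[[g]], paste0(g, "#IR")))
    }
  }
  plastidGeneSet(genes, seqs, features)
}

test_that("code residues are read at the 5th and last motif positions", {
  aa <- paste0(strrep("A", 9), "XXXXTXXXX", strrep("L", 25), "N",
               strrep("A", 10))
  # motif spans residues 10..44: 5th residue is position 14 ('T'),
  # last is 44 ('N')
  arr <- MotifArray("s", data.frame(motif_type = "P", aa_start = 10L,
                                    aa_end = 44L, score = 20))
  pairs <- extractCodeResidues(arr, aa)
  expect_identical(pairs$aa5, "T")
  expect_identical(pairs$aalast, "N")
})

test_that("truncated motifs give unknown pairs and bad coords error", {
  arr <- MotifArray("s", data.frame(motif_type = "P", aa_start = 1L,
                                    aa_end = 4L, score = 20))
  pairs <- extractCodeResidues(arr, strrep("A", 50))
  expect_true(is.na(pairs$aa5) && is.na(pairs$aalast))

  far <- MotifArray("s", data.frame(motif_type = "P", aa_start = 40L,
                                    aa_end = 74L, score = 20))
  expect_error(extractCodeResidues(far, strrep("A", 50)), "beyond")
})

test_that("planted code pairs are extracted verbatim from the cohort", {
  spec <- syntheticSpec(seed = 3, n_sequences = 15, score_noise_sd = 0)
  co <- genPprCohort(spec)
  hits <- filterHits(co$hits)
  for (sid in names(co$code_pairs)) {
    planted <- co$code_pairs[[sid]]
    if (is.null(planted)) next
    arr <- resolveOverlaps(hits[hits$seq_id == sid, ], sid)
    got <- extractCodeResidues(arr, as.character(co$proteins[[sid]]))
    expect_identical(got$aa5, planted$aa5)
    expect_identical(got$aalast, planted$aalast)
  }
})

test_that("code lookup returns packaged sets and defaults to the full set", {
  tab <- pprCodeTable()
  expect_identical(codeLookup("T", "D", tab), "G")
  expect_identical(codeLookup("N", "N", tab), c("C", "U"))
  expect_identical(codeLookup("W", "W", tab), c("A", "C", "G", "U"))
  expect_identical(codeLookup(NA, "D", tab), c("A", "C", "G", "U"))
})

test_that("pattern rendering follows the bracket dialect exactly", {
  p <- buildPattern(list("U", "U", "G", c("C", "U"), "C", "G", "C"))
  expect_identical(patternText(p), "UUG[CU]CGC")
  full3 <- buildPattern(rep(list(c("A", "C", "G", "U")), 3))
  expect_identical(patternText(full3), "[ACGU][ACGU][ACGU]")
})

test_that("every packaged pattern round-trips through parse and render", {
  tt <- aapprTargetTable()
  for (pat in unique(tt$pattern)) {
    p <- parsePattern(pat)
    expect_identical(patternText(p), pat)
  }
  p18 <- parsePattern("UC[GC]UAU[AU][CU][ACGU]G")
  expect_identical(length(p18), 10L)
})

test_that("searching finds printed targets in context", {
  genes <- toy_gene_set(c(
    rbcL = paste0("AAGG", "UUGCCGC", "GGAA"),
    rps16 = paste0("AA", "UCGACAUAGU", "CC")))
  hits <- searchTargets("UUG[CU]CGC", genes, ppr_id = "AaPPR15")
  expect_identical(hits$gene_name, "rbcL")
  expect_identical(hits$matched_sequence, "UUGCCGC")
  expect_identical(hits$match_start, 5L)

  hits6 <- searchTargets("[UC][GC][GC]A[CU][CA]UAG[GU]", genes, "AaPPR6")
  expect_identical(hits6$gene_name, "rps16")
  expect_identical(hits6$matched_sequence, "UCGACAUAGU")
})

test_that("overlapping windows are all reported and empty inputs are fine", {
  genes <- toy_gene_set(c(g1 = "AAAA"))
  hits <- searchTargets("AA", genes)
  expect_identical(hits$match_start, c(1L, 2L, 3L))

  empty <- plastidGeneSet(
    data.frame(record_id = character(), gene_name = character(),
               ir_duplicate = logical(), stringsAsFactors = FALSE),
    Biostrings::RNAStringSet())
  none <- searchTargets("UUG[CU]CGC", empty)
  expect_identical(nrow(none), 0L)
})

test_that("IR duplicates are searched once and flagged", {
  genes <- toy_gene_set(c(rrn23 = paste0("CC", "UUGUCGC", "AA")),
                        ir = "rrn23")
  hits <- searchTargets("UUG[CU]CGC", genes)
  expect_identical(nrow(hits), 1L)
  expect_true(hits$ir_flagged)
})

test_that("feature context is read at the match midpoint", {
  feats <- data.frame(record_id = "g", type = c("CDS", "intron", "CDS"),
                      start = c(1L, 11L, 21L), end = c(10L, 20L, 30L),
                      stringsAsFactors = FALSE)
  seqs <- c(g = paste(rep("A", 30), collapse = ""))
  gs <- plastidGeneSet(data.frame(record_id = "g", gene_name = "g",
                                  ir_duplicate = FALSE), seqs, feats)
  hits <- searchTargets("AAAAA", gs)
  mids <- hits$match_start + 2L
  expected <- ifelse(mids >= 11 & mids <= 20, "intron", "CDS")
  expect_identical(hits$feature_context, expected)
})

test_that("search equals brute-force window enumeration on 5 kb genes", {
  set.seed(55)
  for (rep in 1:4) {
    L <- 5000
    rna <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    genes <- toy_gene_set(c(g1 = rna))
    sets <- lapply(seq_len(sample(5:8, 1)), function(i)
      sort(sample(c("A", "C", "G", "U"), sample(1:3, 1))))
    pat <- buildPattern(sets)
    got <- searchTargets(pat, genes)
    want <- oracle_search_windows(patternPositions(pat), rna)
    expect_identical(got$match_start, want)
    # soundness: every reported window re-validates
    expect_true(all(vapply(got$matched_sequence, patternMatches,
                           logical(1), pattern = pat)))
  }
})

test_that("promiscuity flags strictly above the threshold", {
  mk <- function(n) data.frame(
    ppr_id = "p", gene_name = paste0("g", seq_len(n)),
    feature_context = "CDS", match_start = 1L,
    matched_sequence = "A", ir_flagged = FALSE, stringsAsFactors = FALSE)
  expect_identical(flagPromiscuous(list(p = mk(61))), "p")
  expect_identical(flagPromiscuous(list(p = mk(60))), character(0))
  expect_identical(flagPromiscuous(list(p = mk(0))), character(0))
})

test_that("an all-wildcard pattern is promiscuous with a brute-force count", {
  spec <- syntheticSpec(seed = 17, genome = list(n_genes = 6L,
                                                 planted_sites = 0L))
  genome <- genPlastidGenome(spec)
  pat <- buildPattern(rep(list(c("A", "C", "G", "U")), 7))
  hits <- searchTargets(pat, genome$genes, ppr_id = "wild")
  gt <- geneTable(genome$genes)
  primary <- gt$record_id[!duplicated(gt$gene_name)]
  lens <- Biostrings::width(geneSequences(genome$genes))[
    match(primary, names(geneSequences(genome$genes)))]
  expect_identical(nrow(hits), sum(pmax(lens - 7L + 1L, 0L)))
  expect_identical(flagPromiscuous(list(wild = hits)), "wild")
})

test_that("gene-name categories follow plastid nomenclature", {
  expect_identical(
    classifyTargetGene(c("psbA", "petN", "atpE", "ndhG", "rbcL",
                         "rps12", "rpl33", "trnK-UUU", "rrn23",
                         "rpoC1", "ycf1", "matK")),
    c("photosynthesis", "photosynthesis", "photosynthesis",
      "photosynthesis", "photosynthesis", "ribosomal_protein",
      "ribosomal_protein", "tRNA", "rRNA", "PEP", "unknown_function",
      "other"))
})
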