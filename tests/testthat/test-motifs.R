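write_hits_tsv <- function(tab, path = withr::local_tempfile(
  fileext = ".tsv", .local_envir = parent.frame())) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

test_that("a well-formed hit table parses row for row", {
  tab <- data.frame(seq_id = "s1", motif_type = c("P", "L1", "DYW"),
                    aa_start = c(1L, 36L, 80L), aa_end = c(35L, 70L, 130L),
                    score = c(12.5, 9.1, 44))
  hits <- readHitTable(write_hits_tsv(tab))
  expect_identical(nrow(hits), 3L)
  expect_identical(hits$motif_type, c("P", "L1", "DYW"))
  expect_identical(hits$aa_start, tab$aa_start)
})

test_that("unknown motif names are skipped row-wise with a warning", {
  tab <- data.frame(seq_id = "s1", motif_type = c("P", "PPR_weird", "S1"),
                    aa_start = c(1L, 36L, 71L), aa_end = c(35L, 70L, 105L),
                    score = 10)
  expect_warning(hits <- readHitTable(write_hits_tsv(tab)), "PPR_weird")
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$motif_type, c("P", "S1"))
})

test_that("missing required columns are named in the error", {
  tab <- data.frame(seq_id = "s1", motif_type = "P", aa_start = 1L,
                    aa_end = 35L)
  expect_error(readHitTable(write_hits_tsv(tab)), "score")
})

test_that("the HMMER domtblout dialect is parsed", {
  line <- paste("seqA -  400 PPR_P -  35 1e-20 55.1 0.1 1 1 2e-22 1.5e-20",
                "18.2 0.1 1 35 10 44 9 45 0.9 -")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", line), path)
  hits <- readHitTable(path)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$motif_type, "P")
  expect_identical(hits$aa_start, 10L)
  expect_identical(hits$aa_end, 44L)
  expect_equal(hits$score, 18.2)
  expect_equal(hits$evalue, 1.5e-20)
})

test_that("score filtering is idempotent and honours the E-value gate", {
  set.seed(5)
  hits <- data.frame(
    seq_id = "s", motif_type = sample(motifCatalog(), 60, replace = TRUE),
    aa_start = 1L, aa_end = 35L,
    score = runif(60, -5, 50), stringsAsFactors = FALSE)
  once <- filterHits(hits)
  expect_identical(filterHits(once), once)

  hits$evalue <- 10^runif(60, -20, -5)
  gated <- filterHits(hits)
  expect_true(all(gated$evalue <= 1e-10))
})

test_that("overlap resolution keeps the higher-scoring of identical intervals", {
  hits <- data.frame(seq_id = "s", motif_type = c("P", "P1"),
                     aa_start = 10L, aa_end = 44L, score = c(12, 8),
                     stringsAsFactors = FALSE)
  arr <- resolveOverlaps(hits)
  expect_identical(length(arr), 1L)
  expect_equal(sumScore(arr), 12)
  expect_identical(motifHits(arr)$motif_type, "P")
})

test_that("an empty hit list resolves to an empty array with sum score 0", {
  arr <- resolveOverlaps(data.frame(seq_id = character(),
                                    motif_type = character(),
                                    aa_start = integer(),
                                    aa_end = integer(), score = numeric(),
                                    stringsAsFactors = FALSE), "s")
  expect_identical(length(arr), 0L)
  expect_identical(sumScore(arr), 0)
  expect_identical(motifString(arr), "")
})

test_that("greedy resolution matches an independent greedy trace on fuzz", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    hits <- data.frame(
      seq_id = "s", motif_type = sample(c("P", "P1", "S1"), n, TRUE),
      aa_start = sample(1:400, n, TRUE),
      score = round(rnorm(n, 15, 4), 2), stringsAsFactors = FALSE)
    hits$aa_end <- hits$aa_start + 34L
    arr <- resolveOverlaps(hits, "s")
    got <- motifHits(arr)
    want <- oracle_greedy_trace(hits)
    expect_identical(got$aa_start, want$aa_start)
    expect_identical(got$score, want$score)
    # resolved arrays never overlap, and never beat the total input score
    if (nrow(got) > 1)
      expect_true(all(got$aa_start[-1] > got$aa_end[-nrow(got)]))
    expect_lte(sumScore(arr), sum(hits$score))
  }
})

test_that("on redundant same-locus hit cliques greedy attains the exact optimum", {
  # mutually-overlapping hits at each locus: the redundancy structure that
  # profile sets produce, where picking each clique's maximum is optimal
  set.seed(7)
  for (rep in 1:10) {
    n_loci <- sample(2:4, 1)
    rows <- list()
    for (l in seq_len(n_loci)) {
      base <- 1 + (l - 1) * 60
      k <- sample(2:3, 1)
      for (j in seq_len(k)) {
        st <- base + sample(0:10, 1)
        rows[[length(rows) + 1]] <- data.frame(
          seq_id = "s", motif_type = "P", aa_start = st,
          aa_end = st + 34L, score = round(runif(1, 5, 25), 2),
          stringsAsFactors = FALSE)
      }
    }
    hits <- do.call(rbind, rows)
    arr <- resolveOverlaps(hits, "s")
    expect_equal(sumScore(arr), oracle_exact_intervals(hits))
  }
})
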