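# A construct whose shifted and minus-strand frames are stop-bounded
# without start codons (CTA reverse-complements to the TAG stop), so the
# only complete product is the planted ORF.
planted_tx <- function(n_codons) {
  paste0("TTAATTAATTAA", "ATG", strrep("CTA", n_codons - 1), "TAA",
         "TTAATTAATTAA")
}

test_that("the minimum-length complete ORF is retained, one codon less is not", {
  orfs31 <- extractOrfs(planted_tx(31), "tx", min_aa = 31)
  complete <- orfs31[orfs31$completeness == "complete", ]
  expect_identical(nrow(complete), 1L)
  expect_identical(complete$length_aa, 31L)
  expect_identical(complete$aa_sequence, paste0("M", strrep("L", 30)))

  orfs30 <- extractOrfs(planted_tx(30), "tx", min_aa = 31)
  expect_identical(nrow(orfs30[orfs30$completeness == "complete", ]), 0L)
})

test_that("reported coordinates translate back to the reported peptide", {
  set.seed(101)
  for (rep in 1:5) {
    tx <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
    orfs <- extractOrfs(tx, "tx", min_aa = 15)
    expect_gt(nrow(orfs), 0L)
    for (i in seq_len(nrow(orfs))) {
      nt <- substr(tx, orfs$nt_start[i] + 1L, orfs$nt_end[i])
      if (orfs$strand[i] == "-")
        nt <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(nt)))
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                               no.init.codon = TRUE))
      expect_identical(aa, orfs$aa_sequence[i])
      expect_identical((orfs$nt_end[i] - orfs$nt_start[i]) %% 3L, 0L)
    }
  }
})

test_that("extraction is deterministic and invariant to case and T/U", {
  set.seed(77)
  tx <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  a <- extractOrfs(tx, "tx")
  b <- extractOrfs(tolower(tx), "tx")
  d <- extractOrfs(chartr("T", "U", tx), "tx")
  expect_identical(a, b)
  expect_identical(a, d)
  expect_identical(a, extractOrfs(tx, "tx"))
})

test_that("six-frame scan equals the brute-force codon-walk oracle", {
  set.seed(2024)
  for (rep in 1:6) {
    tx <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
    got <- extractOrfs(tx, "tx", min_aa = 20)
    want <- oracle_orf_scan(tx, min_aa = 20)
    cols <- c("strand", "frame", "nt_start", "nt_end", "aa_sequence",
              "completeness")
    key <- function(d) do.call(paste, c(d[cols], sep = "|"))
    expect_setequal(key(got), key(want))
  }
})

test_that("non-nucleotide characters are rejected with their position", {
  expect_error(extractOrfs("ACGTXACGT", "bad"), "position 5")
  expect_error(extractOrfs("", "empty"), "empty")
})

test_that("ORFs join across a small gap with ceiling(gap/3) X spacers", {
  arr <- function(id, start = 1) MotifArray(id, data.frame(
    motif_type = c("P", "P"), aa_start = c(start, start + 35),
    aa_end = c(start + 34, start + 69), score = c(20, 20)))
  orfs <- data.frame(
    orf_id = c("o1", "o2"), transcript_id = "tx", strand = "+",
    frame = c(0L, 1L), nt_start = c(0L, 309L), nt_end = c(300L, 609L),
    aa_sequence = c(strrep("A", 100), strrep("G", 100)),
    length_aa = c(100L, 100L), completeness = "internal",
    stringsAsFactors = FALSE)
  joined <- joinOrfs(orfs, list(o1 = arr("o1", 30), o2 = arr("o2", 1)),
                     max_gap_nt = 90)
  expect_identical(nrow(joined), 1L)
  expect_identical(joined$x_count, 3L)  # 9-nt gap
  expect_true(joined$hypothetical)
  expect_identical(nchar(joined$aa_sequence), 203L)
  expect_identical(joined$motif_count, 4L)
})

test_that("opposite strands, overlaps and wide gaps refuse to join", {
  arr <- MotifArray("o", data.frame(motif_type = "P", aa_start = 1,
                                    aa_end = 35, score = 20))
  base <- data.frame(
    orf_id = c("o1", "o2"), transcript_id = "tx",
    frame = 0L, aa_sequence = strrep("A", 50), length_aa = 50L,
    completeness = "internal", stringsAsFactors = FALSE)

  opp <- cbind(base, strand = c("+", "-"),
               nt_start = c(0L, 200L), nt_end = c(150L, 350L))
  j <- joinOrfs(opp, list(o1 = arr, o2 = arr))
  expect_identical(nrow(j), 0L)
  expect_identical(attr(j, "refused")$reason, "strand")

  over <- cbind(base, strand = "+",
                nt_start = c(0L, 100L), nt_end = c(150L, 250L))
  j2 <- joinOrfs(over, list(o1 = arr, o2 = arr))
  expect_identical(attr(j2, "refused")$reason, "overlap")

  far <- cbind(base, strand = "+",
               nt_start = c(0L, 400L), nt_end = c(150L, 550L))
  j3 <- joinOrfs(far, list(o1 = arr, o2 = arr))
  expect_identical(attr(j3, "refused")$reason, "gap")
})

test_that("joins are pairwise only: no transitive chains", {
  arr <- function(id) MotifArray(id, data.frame(
    motif_type = c("P", "P"), aa_start = c(1, 36), aa_end = c(35, 70),
    score = c(20, 20)))
  orfs <- data.frame(
    orf_id = c("o1", "o2", "o3"), transcript_id = "tx", strand = "+",
    frame = 0L, nt_start = c(0L, 309L, 618L),
    nt_end = c(300L, 609L, 918L), aa_sequence = strrep("A", 100),
    length_aa = 100L, completeness = "internal", stringsAsFactors = FALSE)
  j <- joinOrfs(orfs, list(o1 = arr("o1"), o2 = arr("o2"),
                           o3 = arr("o3")))
  expect_identical(nrow(j), 1L)
  expect_identical(j$members, "o1,o2")
})

test_that("a planted split array is recovered by joining", {
  # one 4-motif array split across a frameshift into 2+2
  spec_arr <- function(id, types, start) MotifArray(id, data.frame(
    motif_type = types, aa_start = start + 35 * (seq_along(types) - 1),
    aa_end = start + 35 * seq_along(types) - 1,
    score = rep(16, length(types))))
  orfs <- data.frame(
    orf_id = c("a", "b"), transcript_id = "tx", strand = "+",
    frame = c(0L, 2L), nt_start = c(0L, 305L), nt_end = c(300L, 611L),
    aa_sequence = c(strrep("L", 100), strrep("V", 102)),
    length_aa = c(100L, 102L), completeness = "internal",
    stringsAsFactors = FALSE)
  j <- joinOrfs(orfs, list(a = spec_arr("a", c("P1", "L1"), 28),
                           b = spec_arr("b", c("S1", "P1"), 2)))
  expect_identical(j$motif_count, 4L)
})
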