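test_that("generators are pure functions of the spec: reruns are identical", {
  spec <- syntheticSpec(seed = 9, n_sequences = 20)
  a <- genPprCohort(spec)
  b <- genPprCohort(spec)
  expect_identical(as.character(a$proteins), as.character(b$proteins))
  expect_identical(a$hits, b$hits)
  expect_identical(a$truth, b$truth)

  ga <- genPlastidGenome(spec, patterns = list(p = "UUG[CU]CGC"))
  gb <- genPlastidGenome(spec, patterns = list(p = "UUG[CU]CGC"))
  expect_identical(as.character(geneSequences(ga$genes)),
                   as.character(geneSequences(gb$genes)))
  expect_identical(ga$truth, gb$truth)

  ca <- genCtTable(spec)
  cb <- genCtTable(spec)
  expect_identical(ca$ct, cb$ct)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(genPprCohort(syntheticSpec(seed = 2, n_sequences = 5)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("an all-P cohort is recovered 10/10 at zero noise", {
  spec <- syntheticSpec(seed = 4, n_sequences = 10,
                        class_mix = c(P = 1), score_noise_sd = 0)
  co <- genPprCohort(spec)
  arrays <- lapply(split(filterHits(co$hits), filterHits(co$hits)$seq_id),
                   resolveOverlaps)
  ann <- annotateCohort(arrays)
  expect_identical(sum(ann$subfamily == "P"), 10L)
})

test_that("planted target sites are found at their planted offsets", {
  spec <- syntheticSpec(seed = 23, genome = list(planted_sites = 2L))
  genome <- genPlastidGenome(spec, patterns = list(pX = "UUG[CU]CGC"))
  expect_identical(nrow(genome$truth), 2L)
  hits <- searchTargets("UUG[CU]CGC", genome$genes, ppr_id = "pX")
  for (i in seq_len(nrow(genome$truth))) {
    tr <- genome$truth[i, ]
    row <- hits[hits$gene_name == tr$gene_name &
                  hits$match_start == tr$position, ]
    expect_identical(nrow(row), 1L)
    expect_identical(row$matched_sequence, tr$site)
    expect_identical(row$feature_context, tr$feature_context)
  }
})

test_that("a site planted in an IR gene reports exactly one flagged hit", {
  found <- FALSE
  for (seed in 1:30) {
    spec <- syntheticSpec(seed = seed)
    genome <- genPlastidGenome(spec,
                               patterns = list(pI = "GGAUCCAAGGUUCAA"))
    tr <- genome$truth
    if (!tr$ir_duplicate[1]) next
    found <- TRUE
    hits <- searchTargets("GGAUCCAAGGUUCAA", genome$genes, "pI")
    row <- hits[hits$gene_name == tr$gene_name[1] &
                  hits$match_start == tr$position[1], ]
    expect_identical(nrow(row), 1L)
    expect_true(row$ir_flagged)
    break
  }
  expect_true(found)
})

test_that("background hit counts agree with the binomial expectation", {
  # pattern of 7 singletons on uniform-composition genes: expected hits
  # per genome = windows * (1/4)^7; aggregate over 100 seeds within 3 SE
  pat <- parsePattern("UUGCCGC")
  p <- 0.25^7
  observed <- 0
  windows <- 0
  for (seed in 1:100) {
    spec <- syntheticSpec(seed = seed,
                          genome = list(n_genes = 8L, planted_sites = 0L))
    genome <- genPlastidGenome(spec)
    gt <- geneTable(genome$genes)
    primary <- gt$record_id[!duplicated(gt$gene_name)]
    lens <- Biostrings::width(geneSequences(genome$genes))[
      match(primary, names(geneSequences(genome$genes)))]
    windows <- windows + sum(pmax(lens - 7L + 1L, 0L))
    observed <- observed + nrow(searchTargets(pat, genome$genes))
  }
  expected <- windows * p
  se <- sqrt(windows * p * (1 - p))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("zero-noise Ct tables invert to the planted folds exactly", {
  spec <- syntheticSpec(seed = 12, qpcr = list(ct_noise_sd = 0))
  gen <- genCtTable(spec, target_genes = "AaPPR9")
  out <- ddct(gen$ct, "AaPPR9", spec$qpcr$reference_genes, "GL")
  truth <- stats::setNames(gen$truth$fold, gen$truth$tissue)
  expect_equal(stats::setNames(out$rel_expr, out$tissue), truth)
  expect_identical(out$rel_expr[out$tissue == "GL"], 1)
})

test_that("noisy fold changes are recovered within 3 SE over 100 seeds", {
  folds <- matrix(NA_real_, 100, 4,
                  dimnames = list(NULL, c("GL", "GM", "AL", "AM")))
  for (seed in 1:100) {
    spec <- syntheticSpec(seed = seed, qpcr = list(ct_noise_sd = 0.2))
    gen <- genCtTable(spec, target_genes = "g")
    out <- ddct(gen$ct, "g", spec$qpcr$reference_genes, "GL")
    folds[seed, out$tissue] <- out$rel_expr
  }
  planted <- c(GL = 1, GM = 0.6, AL = 4, AM = 1.8)
  for (tt in c("GM", "AL", "AM")) {
    m <- mean(folds[, tt])
    se <- stats::sd(folds[, tt]) / sqrt(nrow(folds))
    # the small lognormal (Jensen) bias of the mean fold is well inside
    # the 3 SE band at sd = 0.2 cycles
    expect_lt(abs(m - planted[[tt]]), 3 * se + 1e-9)
  }
})
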