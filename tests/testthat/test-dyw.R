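test_that("PWM columns are count-and-normalize with pseudocount", {
  pwm <- buildPwm(rep("AC", 4), pseudocount = 1e-4)
  expect_equal(unname(pwm@matrix["A", 1]), 1, tolerance = 1e-3)
  expect_equal(unname(pwm@matrix["C", 2]), 1, tolerance = 1e-3)

  pwm2 <- buildPwm(c("AA", "AC"), pseudocount = 1e-4)
  expect_equal(unname(pwm2@matrix["A", 2]), 0.5, tolerance = 1e-3)
  expect_equal(unname(pwm2@matrix["C", 2]), 0.5, tolerance = 1e-3)
  expect_equal(unname(colSums(pwm2@matrix)), c(1, 1))

  expect_error(buildPwm(c("AA", "ACA")), "equal length")
  expect_warning(buildPwm(c("A-C", "AAC")), "gapped")
})

test_that("generator-scale PWM columns equal a direct counting oracle", {
  set.seed(31)
  block <- vapply(1:231, function(i)
    paste(sample(rownames(dywRegionPwms()$PG_box@matrix), 24,
                 replace = TRUE), collapse = ""), character(1))
  pc <- 0.1
  pwm <- buildPwm(block, pseudocount = pc)
  chars <- do.call(rbind, strsplit(block, ""))
  for (j in c(1, 12, 24)) {
    counts <- table(factor(chars[, j],
                           levels = rownames(pwm@matrix)))
    expect_equal(unname(pwm@matrix[, j]),
                 unname((as.numeric(counts) + pc) / (231 + 20 * pc)))
  }
})

test_that("DP p-values equal exhaustive enumeration for width 2", {
  set.seed(8)
  block <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "D", "E"), 2, replace = TRUE),
          collapse = ""), character(1))
  pwm <- buildPwm(block, region = "w2", pseudocount = 0.2)
  enum <- oracle_pwm_enumeration(pwm)
  aas <- rownames(pwm@matrix)
  # probe a spread of dipeptides, including the best and worst
  probes <- c("AC", "CA", "DE", "WW", "AA", "MK")
  for (pp in probes) {
    got <- scanPwm(pwm, pp, p_cutoff = 1)
    idx <- match(strsplit(pp, "")[[1]], aas)
    s <- sum(round(1000 * log2(pwm@matrix[cbind(idx, 1:2)] /
                                 pwm@background[idx])))
    expect_equal(got$p_value, enum$tail(s), tolerance = 1e-12)
  }
})

test_that("the best window of a near-one-hot width-3 PWM has p = 20^-3", {
  m <- matrix(1e-9, 20, 3, dimnames = list(rownames(
    dywRegionPwms()$PG_box@matrix), NULL))
  m["M", 1] <- m["K", 2] <- m["W", 3] <- 1 - 19e-9
  pwm <- new("RegionPwm", region = "onehot", width = 3L, matrix = m,
             background = rep(1 / 20, 20), offsetHint = 1L)
  hit <- scanPwm(pwm, "MKW", p_cutoff = 1)
  expect_equal(hit$p_value, (1 / 20)^3, tolerance = 1e-9)
})

test_that("sequences shorter than the PWM width yield no hits", {
  pwm <- dywRegionPwms()$PG_box
  expect_identical(nrow(scanPwm(pwm, "MKW")), 0L)
})

test_that("DP tails match Monte-Carlo estimates at full region width", {
  pwm <- dywRegionPwms()$active_site
  set.seed(99)
  n <- 50000
  idx <- matrix(sample(20, n * pwm@width, replace = TRUE,
                       prob = pwm@background), n, pwm@width)
  ints <- round(1000 * log2(pwm@matrix / pwm@background))
  scores <- rowSums(matrix(ints[cbind(as.vector(idx),
                                      rep(seq_len(pwm@width), each = n))],
                           n, pwm@width))
  # a moderate quantile where Monte-Carlo has resolution
  s0 <- ceiling(as.numeric(quantile(scores, 0.999)))
  mc <- mean(scores >= s0)
  se <- sqrt(mc * (1 - mc) / n)
  # exact tail from the same model the scanner uses
  model <- pprscout:::.pwmScoreModel(pwm)
  exact <- model$tail[s0 - model$shift + 1]
  expect_lt(abs(exact - mc), 3 * se + 1e-12)
})

test_that("synthetic full domains grade full, PG box alone grades truncated", {
  pwms <- dywRegionPwms()
  full <- pprscout:::.dywDomainText(pwms, truncated = FALSE)
  pg_only <- pprscout:::.dywDomainText(pwms, truncated = TRUE)
  expect_identical(gradeDyw(full, pwms), "full")
  expect_identical(gradeDyw(pg_only, pwms), "truncated_with_PG")
})

test_that("random sequences grade absent, with the expected false-positive budget", {
  pwms <- dywRegionPwms()
  set.seed(123)
  long <- paste(sample(rownames(pwms$PG_box@matrix), 10031,
                       replace = TRUE), collapse = "")
  n_windows <- nchar(long) - pwms$PG_box@width + 1
  hits <- sum(vapply(pwms, function(p)
    nrow(scanPwm(p, long, p_cutoff = 1e-5)), integer(1)))
  # expected about 3 * 1e-5 * 10000 = 0.3 hits; allow a generous Poisson tail
  expect_lte(hits, 4)

  short <- substr(long, 1, 150)
  expect_identical(gradeDyw(short, pwms), "absent")
})

test_that("grading is monotone: appending missing regions never downgrades", {
  pwms <- dywRegionPwms()
  pg <- pprscout:::.pwmConsensus(pwms$PG_box)
  act <- pprscout:::.pwmConsensus(pwms$active_site)
  ct <- pprscout:::.pwmConsensus(pwms$C_terminal)
  truncated <- paste0(pg, strrep("G", 20))
  expect_identical(gradeDyw(truncated, pwms), "truncated_with_PG")
  completed <- paste0(truncated, act, strrep("G", 10), ct)
  expect_identical(gradeDyw(completed, pwms), "full")
})

test_that("PWMs survive a write/read round trip", {
  pwm <- dywRegionPwms()$C_terminal
  path <- withr::local_tempfile(fileext = ".tsv")
  writePwm(pwm, path)
  back <- readPwm(path, region = "C_terminal", offset_hint = 112L)
  expect_equal(back@matrix, pwm@matrix, tolerance = 1e-12)
  expect_identical(back@width, pwm@width)
})
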